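# ILLUSTRATIVE validation statistics (synthetic): the published per-method
# correlation coefficients and variance ratios are not reproduced here.
# Values follow the qualitative pattern reported for London PM validation:
# temporal correlations larger than spatial ones, most variance ratios
# within ~10% of 1, LUR lowest / dispersion highest temporal variance ratio.
pollutant,method,site_type,alpha_s,alpha_t,gamma_s,gamma_t
PM10,LUR,urban/suburban,0.55,0.80,1.10,0.85
PM10,dispersion,urban/suburban,0.60,0.85,0.95,1.30
PM10,hybrid1,urban/suburban,0.65,0.85,1.05,1.00
PM10,hybrid2,urban/suburban,0.75,0.90,1.00,1.05
PM10,LUR,roadside/kerbside,0.60,0.85,1.05,0.90
PM10,dispersion,roadside/kerbside,0.65,0.85,0.95,1.25
PM10,hybrid1,roadside/kerbside,0.70,0.90,1.05,1.00
PM10,hybrid2,roadside/kerbside,0.80,0.95,1.00,1.02
PM2.5,LUR,urban/suburban,0.50,0.80,1.15,0.85
PM2.5,dispersion,urban/suburban,0.55,0.85,0.95,1.35
PM2.5,hybrid1,urban/suburban,0.65,0.85,1.05,1.00
PM2.5,hybrid2,urban/suburban,0.70,0.90,1.00,1.05
PM2.5,hybrid3,urban/suburban,0.75,0.90,0.95,1.00
PM2.5,ML,urban/suburban,0.70,0.90,0.90,0.95
PM2.5,LUR,roadside/kerbside,0.60,0.85,1.10,0.90
PM2.5,dispersion,roadside/kerbside,0.65,0.85,0.90,1.30
PM2.5,hybrid1,roadside/kerbside,0.75,0.90,1.00,1.00
PM2.5,hybrid2,roadside/kerbside,0.80,0.90,0.95,1.02
PM2.5,hybrid3,roadside/kerbside,0.85,0.95,0.90,1.00
PM2.5,ML,roadside/kerbside,0.80,0.95,0.85,0.95
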