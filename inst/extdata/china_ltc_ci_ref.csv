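year,stratum,indicator,ci,ci_low,ci_high
2013,urban,disabled_residents_per_1000,0.483,0.474,0.490
2013,rural,disabled_residents_per_1000,0.366,0.354,0.375
2013,urban,services_per_resident,0.261,0.247,0.272
2013,rural,services_per_resident,0.318,0.308,0.326
2014,urban,disabled_residents_per_1000,0.465,0.455,0.473
2014,rural,disabled_residents_per_1000,0.279,0.269,0.287
2014,urban,services_per_resident,0.269,0.258,0.277
2014,rural,services_per_resident,0.185,0.172,0.197
2015,urban,disabled_residents_per_1000,0.399,0.391,0.405
2015,rural,disabled_residents_per_1000,0.546,0.533,0.553
2015,urban,services_per_resident,0.384,0.370,0.394
2015,rural,services_per_resident,0.341,0.326,0.355
2016,urban,disabled_residents_per_1000,0.374,0.365,0.381
2016,rural,disabled_residents_per_1000,0.599,0.586,0.606
2016,urban,services_per_resident,0.254,0.245,0.261
2016,rural,services_per_resident,0.206,0.190,0.222
2017,urban,disabled_residents_per_1000,0.329,0.325,0.339
2017,rural,disabled_residents_per_1000,0.499,0.487,0.506
2017,urban,services_per_resident,0.333,0.320,0.377
2017,rural,services_per_resident,0.258,0.240,0.274
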