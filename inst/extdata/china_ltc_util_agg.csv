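year,stratum,region,disabled_residents_per_1000,services_per_resident
2013,urban,Total,1.71,2.86
2013,urban,Eastern,2.79,3.20
2013,urban,Central,0.64,1.64
2013,urban,Western,0.69,2.51
2013,rural,Total,1.16,1.30
2013,rural,Eastern,1.45,2.45
2013,rural,Central,1.26,0.77
2013,rural,Western,0.73,0.70
2014,urban,Total,1.72,2.93
2014,urban,Eastern,2.75,3.52
2014,urban,Central,0.76,1.19
2014,urban,Western,0.71,2.52
2014,rural,Total,0.99,1.44
2014,rural,Eastern,1.36,2.60
2014,rural,Central,0.97,0.87
2014,rural,Western,0.56,0.78
2015,urban,Total,1.75,3.13
2015,urban,Eastern,2.66,4.19
2015,urban,Central,0.86,1.10
2015,urban,Western,0.85,1.52
2015,rural,Total,0.80,1.66
2015,rural,Eastern,1.24,2.90
2015,rural,Central,0.68,1.04
2015,rural,Western,0.39,0.77
2016,urban,Total,1.81,2.67
2016,urban,Eastern,2.76,3.16
2016,urban,Central,0.83,0.89
2016,urban,Western,0.93,3.17
2016,rural,Total,0.85,1.80
2016,rural,Eastern,1.31,3.02
2016,rural,Central,0.71,1.05
2016,rural,Western,0.42,1.11
2017,urban,Total,2.00,2.62
2017,urban,Eastern,3.01,3.18
2017,urban,Central,0.88,0.79
2017,urban,Western,1.16,3.04
2017,rural,Total,0.92,1.96
2017,rural,Eastern,1.45,3.67
2017,rural,Central,0.67,0.88
2017,rural,Western,0.50,1.07
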