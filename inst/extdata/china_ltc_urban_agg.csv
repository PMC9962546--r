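year,region,elderly_pop,institutions_per_1000,beds_per_1000,workers_per_1000
2013,Total,62247,0.11,15.59,1.76
2013,Eastern,29460,0.15,22.82,2.63
2013,Central,18191,0.08,7.88,0.92
2013,Western,14596,0.08,10.63,1.07
2014,Total,67318,0.11,16.01,1.80
2014,Eastern,31425,0.14,21.87,2.42
2014,Central,19078,0.10,10.88,1.49
2014,Western,16815,0.08,10.87,1.01
2015,Total,71275,0.11,16.80,1.86
2015,Eastern,34259,0.13,21.10,1.91
2015,Central,20926,0.10,12.07,2.45
2015,Western,16090,0.10,13.81,0.97
2016,Total,76156,0.12,17.85,1.98
2016,Eastern,36572,0.12,21.83,2.57
2016,Central,22612,0.12,13.89,1.40
2016,Western,16972,0.10,14.55,1.46
2017,Total,82070,0.12,17.54,2.12
2017,Eastern,39363,0.12,21.28,2.66
2017,Central,24419,0.12,14.11,1.59
2017,Western,18288,0.11,14.05,1.67
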