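year,region,elderly_pop,institutions_per_1000,beds_per_1000,workers_per_1000
2013,Total,69455,0.44,39.28,2.37
2013,Eastern,25034,0.37,40.99,2.90
2013,Central,22594,0.52,46.88,2.65
2013,Western,21827,0.43,29.45,1.47
2014,Total,70361,0.33,31.66,1.94
2014,Eastern,25569,0.30,34.27,2.48
2014,Central,22686,0.39,35.98,2.08
2014,Western,22106,0.32,24.19,1.16
2015,Total,72626,0.21,24.39,1.51
2015,Eastern,26101,0.21,28.61,2.12
2015,Central,24281,0.24,24.15,1.42
2015,Western,22244,0.19,19.69,0.88
2016,Total,73951,0.21,24.33,1.52
2016,Eastern,26864,0.20,28.67,2.11
2016,Central,24292,0.24,24.05,1.45
2016,Western,22795,0.18,19.52,0.90
2017,Total,76217,0.20,23.19,1.54
2017,Eastern,27863,0.19,27.23,2.12
2017,Central,25492,0.22,22.78,1.41
2017,Western,22862,0.18,18.72,0.99
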