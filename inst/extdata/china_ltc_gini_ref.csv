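year,stratum,indicator,gini,ci_low,ci_high
2013,urban,institutions,0.227,0.226,0.231
2013,rural,institutions,0.027,0.025,0.028
2013,urban,beds,0.282,0.279,0.284
2013,rural,beds,0.119,0.117,0.122
2013,urban,workers,0.294,0.289,0.300
2013,rural,workers,0.075,0.072,0.078
2014,urban,institutions,0.188,0.186,0.190
2014,rural,institutions,0.033,0.031,0.035
2014,urban,beds,0.229,0.226,0.231
2014,rural,beds,0.134,0.131,0.137
2014,urban,workers,0.266,0.264,0.272
2014,rural,workers,0.097,0.093,0.101
2015,urban,institutions,0.196,0.194,0.199
2015,rural,institutions,0.184,0.181,0.186
2015,urban,beds,0.196,0.194,0.199
2015,rural,beds,0.200,0.197,0.203
2015,urban,workers,0.237,0.234,0.240
2015,rural,workers,0.334,0.330,0.338
2016,urban,institutions,0.210,0.207,0.213
2016,rural,institutions,0.190,0.187,0.193
2016,urban,beds,0.171,0.170,0.173
2016,rural,beds,0.212,0.209,0.215
2016,urban,workers,0.224,0.223,0.229
2016,rural,workers,0.341,0.337,0.344
2017,urban,institutions,0.198,0.194,0.202
2017,rural,institutions,0.189,0.186,0.192
2017,urban,beds,0.168,0.166,0.170
2017,rural,beds,0.214,0.211,0.217
2017,urban,workers,0.206,0.203,0.208
2017,rural,workers,0.316,0.311,0.320
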