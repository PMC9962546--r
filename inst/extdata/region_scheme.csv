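province,region
Beijing,Eastern
Tianjin,Eastern
Hebei,Eastern
Liaoning,Eastern
Shandong,Eastern
Jiangsu,Eastern
Zhejiang,Eastern
Shanghai,Eastern
Fujian,Eastern
Guangdong,Eastern
Hainan,Eastern
Heilongjiang,Central
Jilin,Central
Shanxi,Central
Henan,Central
Anhui,Central
Hubei,Central
Jiangxi,Central
Hunan,Central
Inner Mongolia,Western
Ningxia,Western
Gansu,Western
Shaanxi,Western
Sichuan,Western
Chongqing,Western
Guizhou,Western
Yunnan,Western
Guangxi,Western
Qinghai,Western
Xinjiang,Western
Tibet,Western
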