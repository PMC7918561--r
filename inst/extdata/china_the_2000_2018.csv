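year,THE,ABOVE65,POP,GDP,PER,BED,GGHE,OOP,INF,HCE
2000,458.66,88.21,1267.43,10028.01,4490.80,3177.00,175.591,270.517,32.2,3721
2001,502.59,90.62,1276.27,11086.31,4508.00,3201.00,178.78,301.388,30,3987
2002,579.00,93.77,1284.53,12171.74,4270.00,3136.00,207.478,334.214,29.2,4301
2003,658.41,96.92,1292.27,13742.20,4381.00,3164.00,238.514,367.867,25.5,4606
2004,759.03,98.57,1299.88,16184.02,4486.00,3268.00,288.23,407.135,21.5,5138
2005,865.99,100.55,1307.56,18731.89,4564.05,3367.50,335.713,452.097,19,5771
2006,984.33,104.19,1314.48,21943.85,4728.35,3511.80,400.17,485.356,17.2,6416
2007,1157.40,106.36,1321.29,27009.23,4913.19,3701.10,543.166,509.866,15.3,7572
2008,1453.54,109.56,1328.02,31924.46,5174.48,4038.70,726.035,587.586,14.9,8707
2009,1754.19,113.07,1334.50,34851.77,5535.12,4416.60,920.92,657.116,13.80,9514.00
2010,1998.04,118.94,1340.91,41211.93,5876.16,4786.80,1085.16,705.129,13.10,10919.00
2011,2434.59,122.88,1347.35,48794.02,6202.86,5159.90,1360.70,846.528,12.10,13134.00
2012,2811.90,127.14,1354.04,53858.00,6675.55,5724.80,1573.43,965.632,10.30,14699.00
2013,3166.90,131.61,1360.72,59296.32,7210.58,6181.90,1767.35,1072.934,9.50,16190.00
2014,3531.24,137.55,1367.82,64128.06,7589.79,6601.20,1969.96,1129.541,8.90,17778.00
2015,4097.46,143.86,1374.62,68599.29,8007.54,7015.20,2299.99,1199.265,8.10,19397.00
2016,4634.49,150.03,1382.71,74006.08,8454.40,7410.50,2502.69,1333.79,7.50,21285.00
2017,5259.83,158.31,1390.08,82075.43,8988.23,7940.30,2850.49,1513.36,6.80,22935.00
2018,5912.19,166.58,1395.38,90030.95,9529.18,8404.10,3182.16,1691.20,6.10,25002.00
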