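record_id,ear_tag,test_date,parity,season,dmy_kg,my_morn_kg,my_noon_kg,my_night_kg,fat_pct,protein_pct,bw_kg,dim
a01,ADV001,2023-02-10,2,,25.3,8.35,8.6,8.35,3.87,3.33,561,48
a02,ADV002,2023-03-10,3,,26.8,8.84,9.11,8.85,3.89,3.34,567,66
a03,ADV003,2023-04-10,4,,28.2,9.31,9.59,9.3,3.91,3.32,573,84
a04,ADV004,2023-05-10,1,,29.6,9.77,10.06,9.77,3.85,3.33,579,102
a05,ADV005,2023-06-10,2,,27.4,9.04,9.32,9.04,3.87,3.34,585,120
a06,ADV006,2023-01-10,3,,30.1,9.93,10.23,9.94,3.89,3.32,591,138
a07,ADV007,2023-02-10,4,,28.8,9.5,9.79,9.51,3.91,3.33,555,156
a08,ADV008,2023-03-10,1,,26.1,8.61,8.87,8.62,3.85,3.34,561,174
a09,ADV009,2023-04-10,2,,29.3,9.67,9.96,9.67,3.87,3.32,567,192
a10,ADV010,2023-05-10,3,,27.9,9.21,9.49,9.2,3.89,3.33,573,210
a11,ADV011,2023-06-10,4,,30.5,10.07,10.37,10.06,3.91,3.34,579,228
a12,ADV012,2023-01-10,1,,25.7,8.48,8.74,8.48,3.85,3.32,585,246
a13,ADV013,2023-02-10,2,,28.6,9.44,9.72,9.44,3.87,3.33,591,264
a14,ADV014,2023-03-10,3,,29,9.57,9.86,9.57,3.89,3.34,555,282
a15,,2023-04-12,2,,27.5,9.08,9.35,9.07,3.9,3.35,570,100
a16,ADV016,31/02/2023,3,spring,28.3,9.34,9.62,9.34,3.88,3.3,575,110
a17,ADV017,2023-05-14,,spring,27.8,9.17,9.45,9.18,3.87,3.33,568,95
a18,ADV018,2023-07-14,2,,28.9,9.54,9.83,9.53,3.84,3.36,572,105
a19,ADV019,2023-03-18,2,spring,26.5,,,,,,560,90
a20,ADV005,2023-06-10,1,,70,,23.8,23.1,3.86,3.34,561,88
a21,ADV021,2023-08-05,3,,27.2,8.98,9.25,8.97,,3.34,566,115
a22,ADV022,2023-09-09,2,,70,23.1,23.8,23.1,3.9,3.3,580,125
a23,ADV023,2023-10-02,1,,1.8,0.59,0.61,0.6,3.8,3.3,558,135
a24,ADV024,2023-11-06,2,,27.6,9.11,9.38,9.11,3.83,3.31,567,10
a25,ADV025,2023-12-04,3,,28,9.24,9.52,9.24,3.82,3.3,571,320
a26,ADV026,2023-05-21,2,,45,14.85,15.3,14.85,3.85,3.32,574,150
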