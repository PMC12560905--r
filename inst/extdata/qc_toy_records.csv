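record_id,ear_tag,test_date,parity,season,dmy_kg,my_morn_kg,my_noon_kg,my_night_kg,fat_pct,protein_pct,bw_kg,dim
t01,COW001,2023-02-15,2,,25.4,8.38,8.64,8.38,3.82,3.31,565,50
t02,COW002,2023-03-15,3,,27.1,8.94,9.21,8.95,3.84,3.32,570,60
t03,COW003,2023-04-15,4,,28.9,9.54,9.83,9.53,3.86,3.33,575,70
t04,COW004,2023-05-15,1,,30.2,9.97,10.27,9.96,3.88,3.3,580,80
t05,COW005,2023-06-15,2,,26.6,8.78,9.04,8.78,3.8,3.31,585,90
t06,COW006,2023-01-15,3,,29.5,9.74,10.03,9.73,3.82,3.32,560,100
t07,COW007,2023-02-15,4,,31,10.23,10.54,10.23,3.84,3.33,565,110
t08,COW008,2023-03-15,1,,24.8,8.18,8.43,8.19,3.86,3.3,570,120
t09,COW009,2023-04-15,2,,28.1,9.27,9.55,9.28,3.88,3.31,575,130
t10,COW010,2023-05-15,3,,27.7,9.14,9.42,9.14,3.8,3.32,580,140
t11,COW011,2023-06-15,4,,30.8,10.16,10.47,10.17,3.82,3.33,585,150
t12,COW012,2023-01-15,1,,26.2,8.65,8.91,8.64,3.84,3.3,560,160
t13,COW013,2023-02-15,2,,29.9,9.87,10.17,9.86,3.86,3.31,565,170
t14,COW014,2023-03-15,3,,28.4,9.37,9.66,9.37,3.88,3.32,570,180
t15,COW015,2023-04-15,4,,25.9,8.55,8.81,8.54,3.8,3.33,575,190
t16,COW016,2023-05-15,1,,31.4,10.36,10.68,10.36,3.82,3.3,580,200
t17,,2023-05-10,2,,27,8.91,9.18,8.91,3.9,3.4,570,120
t18,,2023-06-11,3,,28,9.24,9.52,9.24,3.8,3.3,580,130
t19,COW001,2023-02-15,1,,25.4,8.38,8.64,8.38,3.82,3.31,565,50
t20,COW020,2023-07-20,2,,1.5,0.49,0.51,0.5,3.9,3.4,575,140
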