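item_no,item_id,a,b1,b2,b3,b4,sx2,sx2_df,misfit,ld_partners,dif_chi2,dif_df,dif_flag,scale
1,I felt hopeless,4.46,0.38,0.97,1.53,2.23,116.2,88,0,,,,0,frequency
2,I felt worthless,4.17,0.44,1.00,1.57,2.14,102.0,91,0,,,,0,frequency
3,I felt depressed,3.84,-0.11,0.59,1.29,2.15,163.4,120,1,,,,0,frequency
4,I felt unhappy,3.81,-0.39,0.41,1.27,2.06,151.5,120,0,,,,0,frequency
5,I felt that nothing could cheer me up,3.73,0.32,0.94,1.73,2.34,99.4,98,0,,,,0,frequency
6,I felt like a failure,3.73,0.19,0.72,1.58,2.05,137.2,116,0,,,,0,frequency
7,I felt helpless,3.65,0.35,0.94,1.67,2.36,115.0,105,0,,,,0,frequency
8,I felt that I wanted to give up on everything,3.6,0.56,1.1,1.6,2.3,111.3,95,0,,,,0,frequency
9,I felt that I had nothing to look forward to,3.3,0.31,0.8,1.5,2.3,147.1,117,0,,,,0,frequency
10,I felt that my life was empty,3.24,0.28,0.73,1.56,2.11,148.5,120,0,,,,0,frequency
11,I felt emotionally exhausted,3.32,-0.18,0.49,1.27,2.05,126.0,133,0,,,,0,frequency
12,I felt sad,3.20,-0.47,0.37,1.31,2.29,205.7,131,1,,,,0,frequency
13,I felt I had no reason for living,3.1,0.92,1.5,1.9,2.6,83.2,71,0,21;29;35,,,0,frequency
14,I found that things in my life were overwhelming,3.1,-0.09,0.6,1.5,2.3,153.8,138,0,,,,0,frequency
15,I felt that I was not needed,3.08,0.21,0.84,1.55,2.38,162.4,127,0,,,,0,frequency
16,I felt disappointed in myself,3.05,-0.35,0.39,1.31,2.09,199.9,146,1,,,,0,frequency
17,I felt like I needed help for my depression,3.0,0.54,1.01,1.7,2.2,150.2,105,1,,,,0,frequency
18,I had trouble enjoying the things I used to enjoy,2.9,-0.09,0.60,1.4,2.2,165.2,146,0,,,,0,frequency
19,I felt discouraged about the future,2.92,-0.26,0.37,1.31,2.09,159.4,153,0,,,,0,frequency
20,I felt that I was to blame for things,2.88,-0.02,0.73,1.63,2.38,181.3,141,0,,,,0,frequency
21,I wished I were dead and away from it all,2.8,1.01,1.5,2.1,2.6,103.3,71,1,13;29;35,,,0,frequency
22,I felt upset for no reason,2.83,0.23,0.93,1.85,2.93,135.3,117,0,,,,0,frequency
23,I felt that nothing was interesting,2.83,0.06,0.87,1.90,2.64,122.1,122,0,,,,0,frequency
24,I felt I was not as good as other people,2.8,0.15,0.80,1.6,2.3,161.5,130,0,,,,0,frequency
25,I withdrew from other people,2.72,0.04,0.70,1.47,2.30,160.5,144,0,,,,0,frequency
26,I had trouble making decisions,2.71,-0.16,0.75,1.66,2.57,174.8,140,0,32;38,,,0,frequency
27,I had trouble feeling close to people,2.66,-0.12,0.55,1.41,2.24,153.6,155,0,,,,0,frequency
28,I felt pessimistic,2.65,-0.30,0.48,1.38,2.23,198.8,155,0,,,,0,frequency
29,I felt that others would be better off if I were dead,2.6,1.10,1.55,2.4,3.0,70.1,67,0,13;21;35,,,0,frequency
30,I felt lonely,2.54,-0.09,0.60,1.45,2.21,186.0,158,0,,,,0,frequency
31,I felt unloved,2.51,0.26,0.90,1.76,2.48,161.8,136,0,,,,0,frequency
32,I had trouble thinking clearly,2.51,-0.15,0.78,1.84,2.84,178.7,145,0,26;38,,,0,frequency
33,I had mood swings,2.45,-0.32,0.56,1.42,2.32,181.8,153,0,,,,0,frequency
34,I felt like crying,2.44,0.05,0.82,1.67,2.62,178.5,148,0,45,43.4,4,1,frequency
35,I thought about suicide,2.43,1.34,1.80,2.37,2.86,74.9,54,0,13;21;29,,,0,frequency
36,I felt ignored by people,2.41,-0.07,0.73,1.67,2.55,190.2,150,0,,,,0,frequency
37,I felt guilty,2.39,0.07,0.86,1.76,2.54,160.8,139,0,,,,0,frequency
38,I had trouble keeping my mind on what I was doing,2.4,-0.47,0.45,1.7,2.7,187.6,152,0,26;32,,,0,frequency
39,I felt that everything I did was an effort,2.3,-0.21,0.60,1.5,2.4,181.3,165,0,,,,0,frequency
40,My thinking was slower than usual,2.12,-0.22,0.78,2.09,3.11,155.6,139,0,46,,,0,frequency
41,I felt slowed down,2.09,-0.48,0.38,1.47,2.55,226.9,168,1,43;44,,,0,frequency
42,I felt like being alone,1.99,-0.83,-0.19,1.09,2.37,214.8,172,0,,,,0,frequency
43,I got tired more easily than usual,1.99,-0.56,0.24,1.37,2.39,216.3,182,0,41;44,,,0,frequency
44,I felt that I had no energy,1.99,-0.81,0.15,1.20,2.39,192.4,182,0,41;43,,,0,frequency
45,I had crying spells,1.99,0.83,1.49,2.34,3.33,122.0,109,0,34,34.7,4,1,frequency
46,I reacted slowly to things that were done or said,1.9,-0.18,0.93,2.3,3.3,160.8,143,0,40,,,0,frequency
47,I was unable to do many of my usual activities,1.8,0.18,1.08,2.2,3.6,193.7,146,1,,,,0,frequency
48,I had little desire to eat,1.48,0.29,1.39,2.70,3.86,175.3,151,0,,,,0,frequency
49,I disliked the way my body looked,1.39,-1.07,-0.31,0.87,1.82,299.4,217,1,,76.4,4,1,frequency
50,I ate more than usual,1.19,-0.54,0.70,2.33,3.73,227.8,180,1,,,,0,frequency
51,I lost weight without trying,0.57,1.90,4.24,7.03,9.39,151.8,124,0,,,,0,severity
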