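subject,group,region,mean_mm,sd_mm
001,M_under40,whole,0.58,0.44
002,M_under40,whole,0.76,0.51
003,M_under40,whole,0.64,0.43
004,M_under40,whole,0.75,0.46
005,M_under40,whole,0.51,0.33
006,M_under40,whole,0.37,0.21
007,M_under40,whole,0.44,0.3
008,M_under40,whole,0.68,0.46
009,M_under40,whole,0.49,0.28
010,M_under40,whole,0.43,0.3
011,M_over40,whole,0.41,0.31
012,M_over40,whole,0.78,0.49
013,M_over40,whole,0.55,0.4
014,M_over40,whole,0.76,0.54
015,M_over40,whole,0.76,0.51
016,M_over40,whole,0.44,0.29
017,M_over40,whole,0.48,0.29
018,M_over40,whole,0.6,0.36
019,M_over40,whole,0.37,0.23
020,M_over40,whole,0.59,0.48
021,F_under40,whole,0.49,0.35
022,F_under40,whole,0.55,0.41
023,F_under40,whole,0.31,0.27
024,F_under40,whole,0.42,0.33
025,F_under40,whole,0.58,0.33
026,F_under40,whole,0.52,0.37
027,F_under40,whole,0.41,0.29
028,F_under40,whole,0.3,0.2
029,F_under40,whole,0.49,0.35
030,F_under40,whole,0.44,0.3
031,F_over40,whole,0.62,0.43
032,F_over40,whole,0.51,0.37
033,F_over40,whole,0.55,0.35
034,F_over40,whole,0.65,0.47
035,F_over40,whole,0.49,0.34
036,F_over40,whole,0.54,0.39
037,F_over40,whole,0.4,0.31
038,F_over40,whole,0.33,0.21
039,F_over40,whole,0.65,0.49
040,F_over40,whole,0.41,0.28
001,M_under40,articular,0.29,0.21
002,M_under40,articular,0.72,0.39
003,M_under40,articular,0.6,0.33
004,M_under40,articular,0.74,0.36
005,M_under40,articular,0.41,0.25
006,M_under40,articular,0.34,0.19
007,M_under40,articular,0.38,0.21
008,M_under40,articular,0.67,0.33
009,M_under40,articular,0.4,0.23
010,M_under40,articular,0.36,0.21
011,M_over40,articular,0.35,0.22
012,M_over40,articular,0.7,0.32
013,M_over40,articular,0.41,0.22
014,M_over40,articular,0.51,0.34
015,M_over40,articular,0.72,0.32
016,M_over40,articular,0.35,0.2
017,M_over40,articular,0.5,0.23
018,M_over40,articular,0.51,0.25
019,M_over40,articular,0.32,0.21
020,M_over40,articular,0.42,0.27
021,F_under40,articular,0.46,0.3
022,F_under40,articular,0.44,0.31
023,F_under40,articular,0.32,0.21
024,F_under40,articular,0.27,0.17
025,F_under40,articular,0.51,0.26
026,F_under40,articular,0.56,0.32
027,F_under40,articular,0.42,0.29
028,F_under40,articular,0.29,0.19
029,F_under40,articular,0.36,0.21
030,F_under40,articular,0.35,0.23
031,F_over40,articular,0.51,0.27
032,F_over40,articular,0.45,0.27
033,F_over40,articular,0.45,0.24
034,F_over40,articular,0.63,0.37
035,F_over40,articular,0.37,0.21
036,F_over40,articular,0.52,0.33
037,F_over40,articular,0.41,0.28
038,F_over40,articular,0.36,0.2
039,F_over40,articular,0.34,0.25
040,F_over40,articular,0.37,0.2
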