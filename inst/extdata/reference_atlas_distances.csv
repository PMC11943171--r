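subject,side,group,region,mean_mm,sd_mm
001,l,M_under40,whole,0.47,0.37
001,r,M_under40,whole,0.74,0.48
002,l,M_under40,whole,1.01,0.66
002,r,M_under40,whole,0.55,0.5
003,l,M_under40,whole,1.07,0.68
003,r,M_under40,whole,1.39,0.75
004,l,M_under40,whole,1.4,0.99
004,r,M_under40,whole,1.35,0.86
005,l,M_under40,whole,0.83,0.65
005,r,M_under40,whole,1,0.69
006,l,M_under40,whole,0.99,0.59
006,r,M_under40,whole,1.27,0.67
007,l,M_under40,whole,1.02,0.63
007,r,M_under40,whole,1.1,0.55
008,l,M_under40,whole,0.71,0.43
008,r,M_under40,whole,0.56,0.43
009,l,M_under40,whole,0.49,0.35
009,r,M_under40,whole,0.59,0.39
010,l,M_under40,whole,0.69,0.56
010,r,M_under40,whole,0.87,0.63
011,l,M_over40,whole,2.03,1.2
011,r,M_over40,whole,1.97,1.14
012,l,M_over40,whole,1.21,0.82
012,r,M_over40,whole,0.76,0.53
013,l,M_over40,whole,2.08,0.98
013,r,M_over40,whole,2.08,0.99
014,l,M_over40,whole,0.66,0.5
014,r,M_over40,whole,0.86,0.53
015,l,M_over40,whole,1.63,0.87
015,r,M_over40,whole,1.5,0.94
016,l,M_over40,whole,1.33,0.69
016,r,M_over40,whole,1.54,0.82
017,l,M_over40,whole,1.05,0.72
017,r,M_over40,whole,0.86,0.5
018,l,M_over40,whole,0.39,0.29
018,r,M_over40,whole,0.64,0.48
019,l,M_over40,whole,0.52,0.35
019,r,M_over40,whole,0.49,0.42
020,l,M_over40,whole,1.45,0.93
020,r,M_over40,whole,1.45,0.98
021,l,F_under40,whole,0.77,0.45
021,r,F_under40,whole,0.73,0.47
022,l,F_under40,whole,0.54,0.36
022,r,F_under40,whole,0.72,0.55
023,l,F_under40,whole,0.98,0.73
023,r,F_under40,whole,1.14,0.76
024,l,F_under40,whole,1.02,0.63
024,r,F_under40,whole,0.93,0.56
025,l,F_under40,whole,1.38,0.73
025,r,F_under40,whole,1.5,0.91
026,l,F_under40,whole,0.55,0.44
026,r,F_under40,whole,0.68,0.45
027,l,F_under40,whole,1.12,0.62
027,r,F_under40,whole,1.03,0.7
028,l,F_under40,whole,0.94,0.57
028,r,F_under40,whole,1.08,0.59
029,l,F_under40,whole,0.66,0.38
029,r,F_under40,whole,0.92,0.47
030,l,F_under40,whole,0.87,0.5
030,r,F_under40,whole,1.11,0.7
031,l,F_over40,whole,0.89,0.68
031,r,F_over40,whole,0.9,0.6
032,l,F_over40,whole,0.67,0.5
032,r,F_over40,whole,0.71,0.52
033,l,F_over40,whole,0.5,0.36
033,r,F_over40,whole,0.63,0.43
034,l,F_over40,whole,0.73,0.41
034,r,F_over40,whole,0.67,0.41
035,l,F_over40,whole,0.85,0.48
035,r,F_over40,whole,0.83,0.47
036,l,F_over40,whole,1.04,0.71
036,r,F_over40,whole,0.98,0.78
037,l,F_over40,whole,1.03,0.53
037,r,F_over40,whole,0.84,0.52
038,l,F_over40,whole,0.81,0.59
038,r,F_over40,whole,0.92,0.59
039,l,F_over40,whole,0.64,0.45
039,r,F_over40,whole,0.59,0.47
040,l,F_over40,whole,1.56,0.85
040,r,F_over40,whole,1.48,0.72
001,l,M_under40,articular,0.38,0.24
001,r,M_under40,articular,0.43,0.24
002,l,M_under40,articular,0.59,0.36
002,r,M_under40,articular,0.3,0.18
003,l,M_under40,articular,0.83,0.59
003,r,M_under40,articular,0.96,0.55
004,l,M_under40,articular,1.33,0.95
004,r,M_under40,articular,0.95,0.62
005,l,M_under40,articular,0.6,0.49
005,r,M_under40,articular,0.51,0.35
006,l,M_under40,articular,0.66,0.37
006,r,M_under40,articular,0.86,0.47
007,l,M_under40,articular,0.67,0.32
007,r,M_under40,articular,0.77,0.34
008,l,M_under40,articular,0.65,0.36
008,r,M_under40,articular,0.38,0.25
009,l,M_under40,articular,0.38,0.28
009,r,M_under40,articular,0.46,0.28
010,l,M_under40,articular,0.58,0.4
010,r,M_under40,articular,0.63,0.47
011,l,M_over40,articular,1.37,0.69
011,r,M_over40,articular,1.34,0.69
012,l,M_over40,articular,0.89,0.61
012,r,M_over40,articular,0.49,0.38
013,l,M_over40,articular,1.42,0.61
013,r,M_over40,articular,1.49,0.53
014,l,M_over40,articular,0.45,0.3
014,r,M_over40,articular,0.54,0.28
015,l,M_over40,articular,1.33,0.74
015,r,M_over40,articular,1.08,0.7
016,l,M_over40,articular,0.81,0.51
016,r,M_over40,articular,0.88,0.54
017,l,M_over40,articular,0.65,0.4
017,r,M_over40,articular,0.57,0.33
018,l,M_over40,articular,0.29,0.2
018,r,M_over40,articular,0.33,0.27
019,l,M_over40,articular,0.34,0.23
019,r,M_over40,articular,0.43,0.37
020,l,M_over40,articular,0.71,0.42
020,r,M_over40,articular,0.68,0.37
021,l,F_under40,articular,0.56,0.31
021,r,F_under40,articular,0.54,0.31
022,l,F_under40,articular,0.34,0.22
022,r,F_under40,articular,0.51,0.37
023,l,F_under40,articular,0.56,0.3
023,r,F_under40,articular,0.69,0.41
024,l,F_under40,articular,0.76,0.44
024,r,F_under40,articular,0.74,0.41
025,l,F_under40,articular,0.68,0.39
025,r,F_under40,articular,0.71,0.47
026,l,F_under40,articular,0.47,0.34
026,r,F_under40,articular,0.61,0.32
027,l,F_under40,articular,0.62,0.31
027,r,F_under40,articular,0.6,0.3
028,l,F_under40,articular,0.55,0.29
028,r,F_under40,articular,0.72,0.33
029,l,F_under40,articular,0.57,0.28
029,r,F_under40,articular,0.65,0.26
030,l,F_under40,articular,0.68,0.31
030,r,F_under40,articular,0.86,0.43
031,l,F_over40,articular,0.57,0.41
031,r,F_over40,articular,0.52,0.33
032,l,F_over40,articular,0.38,0.26
032,r,F_over40,articular,0.47,0.3
033,l,F_over40,articular,0.32,0.24
033,r,F_over40,articular,0.47,0.29
034,l,F_over40,articular,0.49,0.29
034,r,F_over40,articular,0.45,0.31
035,l,F_over40,articular,0.64,0.37
035,r,F_over40,articular,0.68,0.37
036,l,F_over40,articular,0.53,0.34
036,r,F_over40,articular,0.54,0.37
037,l,F_over40,articular,0.64,0.46
037,r,F_over40,articular,0.5,0.38
038,l,F_over40,articular,0.5,0.31
038,r,F_over40,articular,0.62,0.31
039,l,F_over40,articular,0.4,0.24
039,r,F_over40,articular,0.47,0.32
040,l,F_over40,articular,0.75,0.49
040,r,F_over40,articular,0.76,0.44
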