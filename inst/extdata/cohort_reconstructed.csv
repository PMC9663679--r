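id,gbs,nga,hrel
P001,1,bloody,1
P002,2,bloody,1
P003,3,bloody,1
P004,7,bloody,1
P005,9,bloody,1
P006,9,bloody,1
P007,10,bloody,1
P008,10,bloody,1
P009,10,bloody,1
P010,11,bloody,1
P011,11,bloody,1
P012,11,bloody,1
P013,11,bloody,1
P014,11,bloody,1
P015,11,bloody,1
P016,12,bloody,1
P017,12,bloody,1
P018,12,bloody,1
P019,12,bloody,1
P020,12,bloody,1
P021,15,bloody,1
P022,15,bloody,1
P023,16,bloody,1
P024,17,bloody,1
P025,10,non_bloody,1
P026,11,non_bloody,1
P027,12,non_bloody,1
P028,13,non_bloody,1
P029,13,non_bloody,1
P030,13,non_bloody,1
P031,14,non_bloody,1
P032,15,non_bloody,1
P033,15,non_bloody,1
P034,15,non_bloody,1
P035,16,non_bloody,1
P036,3,bloody,0
P037,6,bloody,0
P038,6,bloody,0
P039,7,bloody,0
P040,7,bloody,0
P041,9,bloody,0
P042,11,bloody,0
P043,11,bloody,0
P044,12,bloody,0
P045,13,bloody,0
P046,15,bloody,0
P047,0,non_bloody,0
P048,0,non_bloody,0
P049,0,non_bloody,0
P050,1,non_bloody,0
P051,2,non_bloody,0
P052,2,non_bloody,0
P053,3,non_bloody,0
P054,3,non_bloody,0
P055,3,non_bloody,0
P056,3,non_bloody,0
P057,3,non_bloody,0
P058,4,non_bloody,0
P059,6,non_bloody,0
P060,6,non_bloody,0
P061,6,non_bloody,0
P062,6,non_bloody,0
P063,7,non_bloody,0
P064,7,non_bloody,0
P065,7,non_bloody,0
P066,7,non_bloody,0
P067,7,non_bloody,0
P068,8,non_bloody,0
P069,8,non_bloody,0
P070,9,non_bloody,0
P071,9,non_bloody,0
P072,9,non_bloody,0
P073,9,non_bloody,0
P074,10,non_bloody,0
P075,10,non_bloody,0
P076,10,non_bloody,0
P077,10,non_bloody,0
P078,10,non_bloody,0
P079,10,non_bloody,0
P080,10,non_bloody,0
P081,10,non_bloody,0
P082,10,non_bloody,0
P083,11,non_bloody,0
P084,11,non_bloody,0
P085,11,non_bloody,0
P086,11,non_bloody,0
P087,11,non_bloody,0
P088,11,non_bloody,0
P089,11,non_bloody,0
P090,11,non_bloody,0
P091,12,non_bloody,0
P092,12,non_bloody,0
P093,12,non_bloody,0
P094,12,non_bloody,0
P095,12,non_bloody,0
P096,12,non_bloody,0
P097,12,non_bloody,0
P098,12,non_bloody,0
P099,12,non_bloody,0
P100,13,non_bloody,0
P101,13,non_bloody,0
P102,13,non_bloody,0
P103,13,non_bloody,0
P104,13,non_bloody,0
P105,13,non_bloody,0
P106,14,non_bloody,0
P107,14,non_bloody,0
P108,14,non_bloody,0
P109,15,non_bloody,0
P110,15,non_bloody,0
P111,16,non_bloody,0
P112,16,non_bloody,0
P113,16,non_bloody,0
P114,16,non_bloody,0
P115,17,non_bloody,0
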