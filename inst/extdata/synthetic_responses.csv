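"person","A32","A21","A9","A17","A4","C16","B8","A20","C23","B7","A33","C21","A2","A22","A30","C24","A28","gender","age"
"P1",3,1,1,2,2,1,3,2,1,2,3,2,3,4,2,2,1,"M",48
"P2",3,3,3,2,3,2,2,3,2,3,3,3,,3,3,2,2,"F",44
"P3",2,2,2,3,4,2,1,2,2,1,1,2,2,2,2,,2,"F",38
"P4",2,3,2,2,1,2,2,1,2,1,1,2,1,4,2,2,2,"M",51
"P5",3,2,2,3,3,2,2,2,2,1,3,2,3,4,2,3,,"F",42
"P6",3,3,3,3,4,2,3,3,3,3,3,3,3,4,3,3,3,"F",65
"P7",3,2,3,2,4,2,2,2,1,2,2,3,3,4,2,2,3,"M",48
"P8",2,1,1,3,1,2,1,2,2,2,2,3,3,3,3,3,2,"F",42
"P9",2,3,2,1,1,2,1,1,2,1,2,3,1,4,1,2,2,"M",49
"P10",2,2,3,1,2,1,1,2,2,3,1,2,2,4,3,3,1,"M",59
"P11",3,2,2,2,3,2,2,2,3,1,1,3,3,3,3,3,3,"F",39
"P12",3,3,3,1,4,3,2,2,3,3,2,1,2,3,3,1,2,"F",20
"P13",2,3,2,1,2,3,3,1,1,1,1,3,2,3,3,2,2,"F",29
"P14",1,2,2,2,4,2,2,2,1,1,1,2,2,3,1,2,2,"M",29
"P15",1,2,2,1,1,1,1,1,1,1,1,2,2,1,1,1,2,"M",55
"P16",,3,2,2,4,2,2,2,2,1,3,2,2,3,2,3,2,"M",53
"P17",3,3,2,3,4,3,3,3,3,,2,3,2,3,2,3,2,"F",28
"P18",2,2,2,2,4,1,2,2,2,1,2,2,2,2,,2,2,"F",51
"P19",2,2,2,2,3,1,1,1,1,1,2,1,2,2,1,1,2,"M",57
"P20",3,2,2,2,2,2,1,2,2,2,2,2,3,3,3,1,2,"F",54
"P21",3,3,3,2,4,3,2,2,2,3,2,3,3,3,3,3,2,"F",21
"P22",2,2,2,1,1,2,1,1,1,1,1,3,3,3,2,3,3,"M",26
"P23",2,1,2,2,1,1,1,2,1,1,2,3,3,2,2,3,2,"F",51
"P24",2,2,2,3,3,3,1,2,2,2,2,3,3,4,3,2,2,"M",61
"P25",3,3,2,2,2,2,1,1,2,2,2,3,3,4,,3,2,"M",20
"P26",1,2,1,2,1,1,1,1,1,2,1,2,3,3,1,1,2,"F",24
"P27",3,,3,3,4,3,2,2,3,3,1,3,2,3,3,2,1,"F",48
"P28",1,1,1,2,1,1,2,2,2,1,1,1,2,1,1,3,2,"M",49
"P29",2,3,3,3,4,3,3,2,3,3,3,3,2,3,2,3,2,"M",44
"P30",3,3,3,3,4,3,3,3,3,3,3,3,3,4,3,3,3,"M",53
"P31",3,3,3,3,3,3,3,3,3,3,2,3,2,3,3,2,2,"M",41
"P32",1,3,2,3,2,2,1,2,3,2,2,2,3,3,2,3,2,"F",64
"P33",2,1,2,1,2,2,1,1,1,2,2,3,2,3,3,1,2,"F",57
"P34",3,2,2,3,2,1,2,2,3,2,1,3,2,2,2,1,1,"F",54
"P35",1,2,1,2,2,1,1,1,1,1,2,2,1,3,2,1,1,"M",44
"P36",2,3,2,2,3,1,2,2,1,2,2,2,1,4,2,2,1,"M",36
"P37",2,3,3,3,4,2,2,3,2,2,3,3,3,3,3,3,3,"F",50
"P38",3,2,1,3,3,1,1,2,1,1,2,3,2,4,3,3,2,"F",25
"P39",3,2,2,3,4,1,3,1,2,2,2,3,3,4,3,3,2,"F",49
"P40",3,2,2,2,3,2,1,2,3,1,1,2,2,4,2,3,1,"M",22
"P41",3,2,3,2,,1,1,1,1,1,2,2,3,3,3,2,1,"M",59
"P42",2,2,2,2,2,2,1,2,2,,1,2,2,2,3,1,2,"M",56
"P43",2,1,2,1,1,1,1,2,2,1,1,3,3,4,3,3,,"F",26
"P44",3,3,3,2,3,2,2,3,2,2,3,1,3,2,2,2,2,"F",59
"P45",2,1,2,2,1,1,1,1,1,1,1,2,2,3,2,2,3,"M",63
"P46",3,3,3,3,3,2,2,2,2,3,2,2,3,2,3,,2,"F",49
"P47",2,1,2,1,3,1,2,2,1,2,2,2,3,4,3,3,3,"F",65
"P48",1,3,1,1,1,1,1,1,2,1,1,2,2,2,1,1,2,"M",24
"P49",3,3,2,2,3,1,2,2,2,2,2,3,3,2,3,2,2,"F",18
"P50",3,3,3,3,4,3,3,3,3,3,2,3,2,4,2,2,3,"F",58
"P51",2,3,3,3,3,2,2,2,1,3,2,3,2,3,3,2,3,"F",65
"P52",3,2,3,3,2,3,3,1,2,2,3,3,2,4,3,3,2,"M",62
"P53",2,3,3,3,4,2,2,1,1,3,2,3,2,4,,3,3,"F",28
"P54",2,3,3,2,3,1,2,2,3,3,3,3,3,3,3,2,3,"F",22
"P55",1,1,1,1,2,1,1,1,1,1,1,1,2,2,2,2,1,"M",64
"P56",2,2,1,2,2,2,2,,2,2,1,3,1,3,2,1,3,"F",28
"P57",2,2,2,2,2,1,2,1,1,2,2,2,1,2,2,2,3,"F",37
"P58",3,3,,3,3,2,3,1,2,1,3,3,,3,3,3,2,"M",52
"P59",3,2,3,1,1,2,1,1,1,2,1,3,2,3,2,3,1,"F",39
"P60",2,2,1,3,2,2,1,1,2,1,1,3,2,1,2,1,1,"M",46
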