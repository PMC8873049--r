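"plot_id","quadrat_id","x","y","area_m2","species","cover"
"plot01","q1",135,195,1,"sp001",3.19
"plot01","q1",135,195,1,"sp002",2.29
"plot01","q1",135,195,1,"sp003",30.33
"plot01","q1",135,195,1,"sp004",0.01
"plot01","q1",135,195,1,"sp005",0.1
"plot01","q1",135,195,1,"sp006",0.04
"plot01","q1",135,195,1,"sp007",30.7
"plot01","q1",135,195,1,"sp008",0
"plot01","q1",135,195,1,"sp009",0.01
"plot01","q1",135,195,1,"sp010",0.85
"plot01","q1",135,195,1,"sp011",0
"plot01","q1",135,195,1,"sp012",4.37
"plot01","q1",135,195,1,"sp013",0.06
"plot01","q1",135,195,1,"sp014",1.13
"plot01","q1",135,195,1,"sp015",0.44
"plot01","q1",135,195,1,"sp016",12.18
"plot01","q1",135,195,1,"sp017",0.62
"plot01","q1",135,195,1,"sp018",0
"plot01","q1",135,195,1,"sp019",1.54
"plot01","q1",135,195,1,"sp020",0.07
"plot01","q1",135,195,1,"sp021",0.04
"plot01","q2",135,195,1,"sp001",0.23
"plot01","q2",135,195,1,"sp002",12.19
"plot01","q2",135,195,1,"sp003",0
"plot01","q2",135,195,1,"sp004",0.32
"plot01","q2",135,195,1,"sp005",4.43
"plot01","q2",135,195,1,"sp006",1.16
"plot01","q2",135,195,1,"sp007",0
"plot01","q2",135,195,1,"sp008",2.21
"plot01","q2",135,195,1,"sp009",2.11
"plot01","q2",135,195,1,"sp010",1.44
"plot01","q2",135,195,1,"sp011",0.13
"plot01","q2",135,195,1,"sp012",0.43
"plot01","q2",135,195,1,"sp013",1.08
"plot01","q2",135,195,1,"sp014",0.18
"plot01","q2",135,195,1,"sp015",0
"plot01","q2",135,195,1,"sp016",30.57
"plot01","q2",135,195,1,"sp017",0.86
"plot01","q2",135,195,1,"sp018",0
"plot01","q2",135,195,1,"sp019",0
"plot01","q2",135,195,1,"sp020",0.05
"plot01","q2",135,195,1,"sp021",0
"plot01","q2",135,195,1,"sp022",0.02
"plot01","q3",135,195,1,"sp001",2.52
"plot01","q3",135,195,1,"sp002",0
"plot01","q3",135,195,1,"sp003",0.05
"plot01","q3",135,195,1,"sp004",4.7
"plot01","q3",135,195,1,"sp005",8
"plot01","q3",135,195,1,"sp006",0.29
"plot01","q3",135,195,1,"sp007",0.04
"plot01","q3",135,195,1,"sp008",0
"plot01","q3",135,195,1,"sp009",14.05
"plot01","q3",135,195,1,"sp010",0.26
"plot01","q3",135,195,1,"sp011",2.46
"plot01","q3",135,195,1,"sp012",8.49
"plot01","q3",135,195,1,"sp013",0.64
"plot01","q3",135,195,1,"sp014",0
"plot01","q3",135,195,1,"sp015",0.07
"plot01","q3",135,195,1,"sp016",2.08
"plot01","q3",135,195,1,"sp017",0.03
"plot01","q3",135,195,1,"sp018",36.49
"plot01","q3",135,195,1,"sp019",0.01
"plot01","q3",135,195,1,"sp020",0
"plot02","q1",135,315,1,"sp001",4.09
"plot02","q1",135,315,1,"sp002",0.7
"plot02","q1",135,315,1,"sp003",0.15
"plot02","q1",135,315,1,"sp004",0.53
"plot02","q1",135,315,1,"sp005",3.15
"plot02","q1",135,315,1,"sp006",0.01
"plot02","q1",135,315,1,"sp007",0
"plot02","q1",135,315,1,"sp008",0.06
"plot02","q1",135,315,1,"sp009",0.02
"plot02","q1",135,315,1,"sp010",0
"plot02","q1",135,315,1,"sp011",0.01
"plot02","q1",135,315,1,"sp012",0
"plot02","q1",135,315,1,"sp013",16.88
"plot02","q1",135,315,1,"sp014",0
"plot02","q1",135,315,1,"sp015",1.94
"plot02","q1",135,315,1,"sp016",0.1
"plot02","q1",135,315,1,"sp017",1.34
"plot02","q1",135,315,1,"sp018",0.23
"plot02","q1",135,315,1,"sp019",0.01
"plot02","q1",135,315,1,"sp020",6.13
"plot02","q1",135,315,1,"sp021",0
"plot02","q1",135,315,1,"sp022",0.11
"plot02","q1",135,315,1,"sp023",0
"plot02","q1",135,315,1,"sp024",1.55
"plot02","q1",135,315,1,"sp025",5
"plot02","q1",135,315,1,"sp026",0.81
"plot02","q1",135,315,1,"sp027",1.63
"plot02","q1",135,315,1,"sp028",0.46
"plot02","q2",135,315,1,"sp001",0.99
"plot02","q2",135,315,1,"sp002",8.75
"plot02","q2",135,315,1,"sp003",10.32
"plot02","q2",135,315,1,"sp004",0.01
"plot02","q2",135,315,1,"sp005",0.69
"plot02","q2",135,315,1,"sp006",0.5
"plot02","q2",135,315,1,"sp007",0
"plot02","q2",135,315,1,"sp008",0
"plot02","q2",135,315,1,"sp009",0.4
"plot02","q2",135,315,1,"sp010",3.07
"plot02","q2",135,315,1,"sp011",1.57
"plot02","q2",135,315,1,"sp012",0
"plot02","q2",135,315,1,"sp013",3.54
"plot02","q2",135,315,1,"sp014",0
"plot02","q2",135,315,1,"sp015",0.44
"plot02","q2",135,315,1,"sp016",0.02
"plot02","q2",135,315,1,"sp017",0.24
"plot02","q2",135,315,1,"sp018",0
"plot02","q2",135,315,1,"sp019",0.65
"plot02","q2",135,315,1,"sp020",0.08
"plot02","q2",135,315,1,"sp021",0.02
"plot02","q2",135,315,1,"sp022",0.02
"plot02","q2",135,315,1,"sp023",0.67
"plot02","q2",135,315,1,"sp024",0.03
"plot02","q2",135,315,1,"sp025",7.88
"plot02","q2",135,315,1,"sp026",0.01
"plot02","q2",135,315,1,"sp027",0.85
"plot02","q2",135,315,1,"sp028",0.09
"plot02","q2",135,315,1,"sp029",0.47
"plot02","q2",135,315,1,"sp030",1.02
"plot02","q3",135,315,1,"sp001",0
"plot02","q3",135,315,1,"sp002",0
"plot02","q3",135,315,1,"sp003",0.01
"plot02","q3",135,315,1,"sp004",0.09
"plot02","q3",135,315,1,"sp005",0.1
"plot02","q3",135,315,1,"sp006",0
"plot02","q3",135,315,1,"sp007",0.05
"plot02","q3",135,315,1,"sp008",0.67
"plot02","q3",135,315,1,"sp009",0.5
"plot02","q3",135,315,1,"sp010",0.03
"plot02","q3",135,315,1,"sp011",1.54
"plot02","q3",135,315,1,"sp012",8.04
"plot02","q3",135,315,1,"sp013",0
"plot02","q3",135,315,1,"sp014",3.42
"plot02","q3",135,315,1,"sp015",2.01
"plot02","q3",135,315,1,"sp016",4.04
"plot02","q3",135,315,1,"sp017",0.54
"plot02","q3",135,315,1,"sp018",0
"plot02","q3",135,315,1,"sp019",0.01
"plot02","q3",135,315,1,"sp020",27.28
"plot02","q3",135,315,1,"sp021",0.51
"plot02","q3",135,315,1,"sp022",0
"plot02","q3",135,315,1,"sp023",0.05
"plot02","q3",135,315,1,"sp024",0
"plot02","q3",135,315,1,"sp025",0
"plot02","q3",135,315,1,"sp026",0.83
"plot02","q3",135,315,1,"sp027",4.08
"plot02","q3",135,315,1,"sp028",3.55
"plot02","q3",135,315,1,"sp029",0.58
"plot02","q3",135,315,1,"sp030",0.37
"plot03","q1",435,435,1,"sp001",0
"plot03","q1",435,435,1,"sp002",0
"plot03","q1",435,435,1,"sp003",34.24
"plot03","q1",435,435,1,"sp004",11.69
"plot03","q1",435,435,1,"sp005",0
"plot03","q1",435,435,1,"sp006",0
"plot03","q1",435,435,1,"sp007",1.74
"plot03","q2",435,435,1,"sp001",0
"plot03","q2",435,435,1,"sp002",0
"plot03","q2",435,435,1,"sp003",0
"plot03","q2",435,435,1,"sp004",9.91
"plot03","q2",435,435,1,"sp005",0.79
"plot03","q2",435,435,1,"sp006",49.76
"plot03","q2",435,435,1,"sp007",9.49
"plot03","q2",435,435,1,"sp008",0.18
"plot03","q3",435,435,1,"sp001",6.12
"plot03","q3",435,435,1,"sp002",0.01
"plot03","q3",435,435,1,"sp003",0
"plot03","q3",435,435,1,"sp004",57.87
"plot03","q3",435,435,1,"sp005",0
"plot03","q3",435,435,1,"sp006",0.22
"plot04","q1",345,405,1,"sp001",0
"plot04","q1",345,405,1,"sp002",0
"plot04","q1",345,405,1,"sp003",69.42
"plot04","q1",345,405,1,"sp004",4.56
"plot04","q1",345,405,1,"sp005",2.78
"plot04","q1",345,405,1,"sp006",0
"plot04","q1",345,405,1,"sp007",4.26
"plot04","q1",345,405,1,"sp008",3.74
"plot04","q1",345,405,1,"sp009",2.56
"plot04","q1",345,405,1,"sp010",0.02
"plot04","q2",345,405,1,"sp001",0
"plot04","q2",345,405,1,"sp002",74.8
"plot04","q2",345,405,1,"sp003",0.5
"plot04","q2",345,405,1,"sp004",0.01
"plot04","q2",345,405,1,"sp005",0.12
"plot04","q2",345,405,1,"sp006",3.74
"plot04","q2",345,405,1,"sp007",1.64
"plot04","q2",345,405,1,"sp008",0.73
"plot04","q2",345,405,1,"sp009",0
"plot04","q3",345,405,1,"sp001",0
"plot04","q3",345,405,1,"sp002",0
"plot04","q3",345,405,1,"sp003",0
"plot04","q3",345,405,1,"sp004",0
"plot04","q3",345,405,1,"sp005",0
"plot04","q3",345,405,1,"sp006",1.38
"plot04","q3",345,405,1,"sp007",0
"plot04","q3",345,405,1,"sp008",0.63
"plot04","q3",345,405,1,"sp009",0
"plot04","q3",345,405,1,"sp010",0
"plot04","q3",345,405,1,"sp011",0.89
"plot04","q3",345,405,1,"sp012",58.53
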