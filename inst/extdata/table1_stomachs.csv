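"stomach_id","tl_mm"
"S01",303.483333333333
"S02",310.45
"S03",317.416666666667
"S04",324.383333333333
"S05",331.35
"S06",338.316666666667
"S07",345.283333333333
"S08",352.25
"S09",359.216666666667
"S10",366.183333333333
"S11",374.642857142857
"S12",384.595238095238
"S13",394.547619047619
"S14",404.5
"S15",414.452380952381
"S16",424.404761904762
"S17",434.357142857143
"S18",441.821428571429
"S19",446.797619047619
"S20",451.77380952381
"S21",456.75
"S22",461.726190476191
"S23",466.702380952381
"S24",471.678571428571
"S25",476.654761904762
"S26",481.630952380952
"S27",486.607142857143
"S28",491.583333333333
"S29",496.559523809524
"S30",501.535714285714
"S31",506.511904761905
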