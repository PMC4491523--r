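"time_s","flow_m3s"
0,0
0.003125,1.87358845994312e-05
0.00625,3.74404225623457e-05
0.009375,5.60823196976618e-05
0.0125,7.46303866174229e-05
0.015625,9.3053590919143e-05
0.01875,0.000111321109105503
0.021875,0.000129402378154532
0.025,0.000147267146653994
0.028125,0.000164885525414422
0.03125,0.00018222803747613
0.034375,0.000199265667426529
0.0375,0.000215969909945235
0.040625,0.000232312817495759
0.04375,0.000248267047083971
0.046875,0.000263805906005123
0.05,0.000278903396502882
0.053125,0.000293534259265663
0.05625,0.000307674015687476
0.059375,0.000321299008822601
0.0625,0.000334386442965553
0.065625,0.000346914421790121
0.06875,0.000358861984983682
0.071875,0.000370209143315477
0.075,0.000380936912080204
0.078125,0.000391027342860946
0.08125,0.000400463553558311
0.084375,0.000409229756635541
0.0875,0.000417311285532322
0.090625,0.000424694619203119
0.09375,0.000431367404738965
0.096875,0.000437318478034871
0.1,0.000442537882468265
0.103125,0.000447016885557223
0.10625,0.000450747993570608
0.109375,0.000453724964065685
0.1125,0.000455942816332229
0.115625,0.000457397839725647
0.11875,0.000458087599875191
0.121875,0.000458010942756849
0.125,0.000457167996624123
0.128125,0.000455560171793453
0.13125,0.000453190158284638
0.134375,0.000450061921320222
0.1375,0.000446180694691359
0.140625,0.000441552972001258
0.14375,0.000436186495800867
0.146875,0.000430090244634965
0.15,0.000423274418020334
0.153125,0.000415750419381152
0.15625,0.000407530836970152
0.159375,0.000398629422807463
0.1625,0.000389061069672381
0.165625,0.000378841786186553
0.16875,0.000367988670030273
0.171875,0.00035651987933669
0.175,0.000344454602311797
0.178125,0.000331813025131024
0.18125,0.000318616298166151
0.184375,0.000304886500599038
0.1875,0.000290646603481385
0.190625,0.000275920431302322
0.19375,0.000260732622128129
0.196875,0.000245108586380777
0.2,0.000229074464324256
0.203125,0.000212657082329815
0.20625,0.000195883907993298
0.209375,0.000178783004179651
0.2125,0.0001613829820715
0.215625,0.000143712953300353
0.21875,0.000125802481240502
0.221875,0.000107681531547133
0.225,8.93804220213822e-05
0.228125,7.0929771886222e-05
0.23125,5.23604505580506e-05
0.234375,3.37035259996831e-05
0.2375,1.49902127411586e-05
0.240625,0
0.24375,0
0.246875,0
0.25,0
0.253125,0
0.25625,0
0.259375,0
0.2625,0
0.265625,0
0.26875,0
0.271875,0
0.275,0
0.278125,0
0.28125,0
0.284375,0
0.2875,0
0.290625,0
0.29375,0
0.296875,0
0.3,0
0.303125,0
0.30625,0
0.309375,0
0.3125,0
0.315625,0
0.31875,0
0.321875,0
0.325,0
0.328125,0
0.33125,0
0.334375,0
0.3375,0
0.340625,0
0.34375,0
0.346875,0
0.35,0
0.353125,0
0.35625,0
0.359375,0
0.3625,0
0.365625,0
0.36875,0
0.371875,0
0.375,0
0.378125,0
0.38125,0
0.384375,0
0.3875,0
0.390625,0
0.39375,0
0.396875,0
0.4,0
0.403125,0
0.40625,0
0.409375,0
0.4125,0
0.415625,0
0.41875,0
0.421875,0
0.425,0
0.428125,0
0.43125,0
0.434375,0
0.4375,0
0.440625,0
0.44375,0
0.446875,0
0.45,0
0.453125,0
0.45625,0
0.459375,0
0.4625,0
0.465625,0
0.46875,0
0.471875,0
0.475,0
0.478125,0
0.48125,0
0.484375,0
0.4875,0
0.490625,0
0.49375,0
0.496875,0
0.5,0
0.503125,0
0.50625,0
0.509375,0
0.5125,0
0.515625,0
0.51875,0
0.521875,0
0.525,0
0.528125,0
0.53125,0
0.534375,0
0.5375,0
0.540625,0
0.54375,0
0.546875,0
0.55,0
0.553125,0
0.55625,0
0.559375,0
0.5625,0
0.565625,0
0.56875,0
0.571875,0
0.575,0
0.578125,0
0.58125,0
0.584375,0
0.5875,0
0.590625,0
0.59375,0
0.596875,0
0.6,0
0.603125,0
0.60625,0
0.609375,0
0.6125,0
0.615625,0
0.61875,0
0.621875,0
0.625,0
0.628125,0
0.63125,0
0.634375,0
0.6375,0
0.640625,0
0.64375,0
0.646875,0
0.65,0
0.653125,0
0.65625,0
0.659375,0
0.6625,0
0.665625,0
0.66875,0
0.671875,0
0.675,0
0.678125,0
0.68125,0
0.684375,0
0.6875,0
0.690625,0
0.69375,0
0.696875,0
0.7,0
0.703125,0
0.70625,0
0.709375,0
0.7125,0
0.715625,0
0.71875,0
0.721875,0
0.725,0
0.728125,0
0.73125,0
0.734375,0
0.7375,0
0.740625,0
0.74375,0
0.746875,0
0.75,0
0.753125,0
0.75625,0
0.759375,0
0.7625,0
0.765625,0
0.76875,0
0.771875,0
0.775,0
0.778125,0
0.78125,0
0.784375,0
0.7875,0
0.790625,0
0.79375,0
0.796875,0
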