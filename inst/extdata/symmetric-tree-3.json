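{
  "units": "SI",
  "globals": {
    "density": 1050,
    "viscosity": 0.004,
    "profile_order": 9,
    "diastolic_pressure": 0
  },
  "segments": [
    {
      "id": "root",
      "parent": null,
      "length": 0.0599779127240181,
      "radius_in": 0.0115497766332328,
      "radius_out": 0.0115497766332328,
      "beta_in": 1068.59674199187,
      "beta_out": 1068.59674199187,
      "generation": 0
    },
    {
      "id": "root_1",
      "parent": "root",
      "length": 0.0527757670274377,
      "radius_in": 0.00903035267056991,
      "radius_out": 0.00903035267056991,
      "beta_in": 1248.90518429614,
      "beta_out": 1248.90518429614,
      "generation": 1
    },
    {
      "id": "root_2",
      "parent": "root",
      "length": 0.0550139537338167,
      "radius_in": 0.00895464124802178,
      "radius_out": 0.00895464124802178,
      "beta_in": 1197.4209909804,
      "beta_out": 1197.4209909804,
      "generation": 1
    },
    {
      "id": "root_1_1",
      "parent": "root_1",
      "length": 0.0425179240045566,
      "radius_in": 0.00666877400029697,
      "radius_out": 0.00666877400029697,
      "beta_in": 1097.22552162049,
      "beta_out": 1097.22552162049,
      "generation": 2
    },
    {
      "id": "root_1_2",
      "parent": "root_1",
      "length": 0.0452743600550741,
      "radius_in": 0.00701968040321556,
      "radius_out": 0.00701968040321556,
      "beta_in": 1417.92284793308,
      "beta_out": 1417.92284793308,
      "generation": 2
    },
    {
      "id": "root_2_1",
      "parent": "root_2",
      "length": 0.0463651154829506,
      "radius_in": 0.00693436569381109,
      "radius_out": 0.00693436569381109,
      "beta_in": 1333.82731633573,
      "beta_out": 1333.82731633573,
      "generation": 2
    },
    {
      "id": "root_2_2",
      "parent": "root_2",
      "length": 0.0413534205276165,
      "radius_in": 0.00700197729236736,
      "radius_out": 0.00700197729236736,
      "beta_in": 1400.1333234429,
      "beta_out": 1400.1333234429,
      "generation": 2
    },
    {
      "id": "root_1_1_1",
      "parent": "root_1_1",
      "length": 0.0377417078553359,
      "radius_in": 0.0050077733336295,
      "radius_out": 0.0050077733336295,
      "beta_in": 1047.97086641489,
      "beta_out": 1047.97086641489,
      "generation": 3
    },
    {
      "id": "root_1_1_2",
      "parent": "root_1_1",
      "length": 0.0346399226237495,
      "radius_in": 0.00526439807068177,
      "radius_out": 0.00526439807068177,
      "beta_in": 1345.45600016677,
      "beta_out": 1345.45600016677,
      "generation": 3
    },
    {
      "id": "root_1_2_1",
      "parent": "root_1_2",
      "length": 0.03547512617455,
      "radius_in": 0.00513579104664353,
      "radius_out": 0.00513579104664353,
      "beta_in": 1188.9473480535,
      "beta_out": 1188.9473480535,
      "generation": 3
    },
    {
      "id": "root_1_2_2",
      "parent": "root_1_2",
      "length": 0.0361760742440008,
      "radius_in": 0.00530378643306988,
      "radius_out": 0.00530378643306988,
      "beta_in": 1396.54853532946,
      "beta_out": 1396.54853532946,
      "generation": 3
    },
    {
      "id": "root_2_1_1",
      "parent": "root_2_1",
      "length": 0.0339786440481716,
      "radius_in": 0.00523313921078,
      "radius_out": 0.00523313921078,
      "beta_in": 1305.98242584458,
      "beta_out": 1305.98242584458,
      "generation": 3
    },
    {
      "id": "root_2_1_2",
      "parent": "root_2_1",
      "length": 0.036154106439702,
      "radius_in": 0.00528842273329665,
      "radius_out": 0.00528842273329665,
      "beta_in": 1376.43817985128,
      "beta_out": 1376.43817985128,
      "generation": 3
    },
    {
      "id": "root_2_2_1",
      "parent": "root_2_2",
      "length": 0.0390270493500296,
      "radius_in": 0.00519453855211471,
      "radius_out": 0.00519453855211471,
      "beta_in": 1258.52185682112,
      "beta_out": 1258.52185682112,
      "generation": 3
    },
    {
      "id": "root_2_2_2",
      "parent": "root_2_2",
      "length": 0.0359062615448719,
      "radius_in": 0.00518492160909557,
      "radius_out": 0.00518492160909557,
      "beta_in": 1246.91504966601,
      "beta_out": 1246.91504966601,
      "generation": 3
    }
  ],
  "terminals": [
    {
      "segment": "root_1_1_1",
      "r1": 99932156.0575375,
      "r2": 1104333488.5649,
      "c": 1.64196022435183e-09,
      "p_out": 0
    },
    {
      "segment": "root_1_1_2",
      "r1": 99932156.0575375,
      "r2": 989785984.834557,
      "c": 1.81455755742922e-09,
      "p_out": 0
    },
    {
      "segment": "root_1_2_1",
      "r1": 99932156.0575375,
      "r2": 1045045289.33113,
      "c": 1.72698274187598e-09,
      "p_out": 0
    },
    {
      "segment": "root_1_2_2",
      "r1": 99932156.0575375,
      "r2": 973660587.062115,
      "c": 1.84181227071045e-09,
      "p_out": 0
    },
    {
      "segment": "root_2_1_1",
      "r1": 99932156.0575375,
      "r2": 1002843188.09304,
      "c": 1.79307263125885e-09,
      "p_out": 0
    },
    {
      "segment": "root_2_1_2",
      "r1": 99932156.0575375,
      "r2": 979907559.65378,
      "c": 1.83115721644016e-09,
      "p_out": 0
    },
    {
      "segment": "root_2_2_1",
      "r1": 99932156.0575375,
      "r2": 1019293548.50686,
      "c": 1.76671808015083e-09,
      "p_out": 0
    },
    {
      "segment": "root_2_2_2",
      "r1": 99932156.0575375,
      "r2": 1023449257.18857,
      "c": 1.76018248540336e-09,
      "p_out": 0
    }
  ]
}
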