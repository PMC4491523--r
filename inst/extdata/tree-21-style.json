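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
      "id": "aorta_asc",
      "parent": null,
      "length": 0.0392757201850414,
      "radius_in": 0.0129387058518827,
      "radius_out": 0.0110167598522902,
      "beta_in": 1080.20124317583,
      "beta_out": 919.745593140742,
      "generation": 0
    },
    {
      "id": "arch_a",
      "parent": "aorta_asc",
      "length": 0.0236511631114408,
      "radius_in": 0.0110167598522902,
      "radius_out": 0.0100420745972395,
      "beta_in": 839.097760134084,
      "beta_out": 764.860305082478,
      "generation": 0
    },
    {
      "id": "arch_b",
      "parent": "arch_a",
      "length": 0.0370483044882864,
      "radius_in": 0.0100420745972395,
      "radius_out": 0.0093115978859365,
      "beta_in": 713.139929378342,
      "beta_out": 661.264980106969,
      "generation": 0
    },
    {
      "id": "thoracic_a",
      "parent": "arch_b",
      "length": 0.0510951956248283,
      "radius_in": 0.0093115978859365,
      "radius_out": 0.00882279910294712,
      "beta_in": 860.060066209679,
      "beta_out": 814.912464389803,
      "generation": 0
    },
    {
      "id": "thoracic_b",
      "parent": "thoracic_a",
      "length": 0.100237716129422,
      "radius_in": 0.00882279910294712,
      "radius_out": 0.0083737733450532,
      "beta_in": 854.123892435381,
      "beta_out": 810.654283339557,
      "generation": 0
    },
    {
      "id": "abdominal_a",
      "parent": "thoracic_b",
      "length": 0.0503874625046551,
      "radius_in": 0.0083737733450532,
      "radius_out": 0.00730807482339442,
      "beta_in": 877.991379956275,
      "beta_out": 766.252731548589,
      "generation": 0
    },
    {
      "id": "abdominal_b",
      "parent": "abdominal_a",
      "length": 0.0200140537805855,
      "radius_in": 0.00730807482339442,
      "radius_out": 0.0075287100007385,
      "beta_in": 780.30054167189,
      "beta_out": 803.858284655355,
      "generation": 0
    },
    {
      "id": "abdominal_c",
      "parent": "abdominal_b",
      "length": 0.0208442891418934,
      "radius_in": 0.0075287100007385,
      "radius_out": 0.00615248970393091,
      "beta_in": 894.555998016864,
      "beta_out": 731.03447560718,
      "generation": 0
    },
    {
      "id": "abdominal_d",
      "parent": "abdominal_c",
      "length": 0.0206197403863072,
      "radius_in": 0.00615248970393091,
      "radius_out": 0.00596073951914907,
      "beta_in": 624.479165105765,
      "beta_out": 605.01647584276,
      "generation": 0
    },
    {
      "id": "abdominal_e",
      "parent": "abdominal_d",
      "length": 0.0533735795167834,
      "radius_in": 0.00596073951914907,
      "radius_out": 0.00566270254319161,
      "beta_in": 771.821718094628,
      "beta_out": 733.230632189896,
      "generation": 0
    },
    {
      "id": "innominate",
      "parent": "aorta_asc",
      "length": 0.0348654345108569,
      "radius_in": 0.00587437409218401,
      "radius_out": 0.00528693668296561,
      "beta_in": 551.970288042217,
      "beta_out": 496.773259237996,
      "generation": 1
    },
    {
      "id": "carotid_l",
      "parent": "arch_a",
      "length": 0.137741801602319,
      "radius_in": 0.00377221929888055,
      "radius_out": 0.00339499736899249,
      "beta_in": 463.450883337108,
      "beta_out": 417.105795003397,
      "generation": 1
    },
    {
      "id": "subclavian_l_a",
      "parent": "arch_b",
      "length": 0.0363536341799796,
      "radius_in": 0.00452843270480633,
      "radius_out": 0.0040755894343257,
      "beta_in": 573.011613687074,
      "beta_out": 515.710452318367,
      "generation": 1
    },
    {
      "id": "intercostals",
      "parent": "thoracic_a",
      "length": 0.0748138950407505,
      "radius_in": 0.00307902460432053,
      "radius_out": 0.00277112214388847,
      "beta_in": 414.338322036325,
      "beta_out": 372.904489832693,
      "generation": 1
    },
    {
      "id": "celiac_a",
      "parent": "thoracic_b",
      "length": 0.0208388567395508,
      "radius_in": 0.00370388569909707,
      "radius_out": 0.00333349712918736,
      "beta_in": 446.505075008551,
      "beta_out": 401.854567507696,
      "generation": 1
    },
    {
      "id": "mesenteric_sup",
      "parent": "abdominal_a",
      "length": 0.0628852679124102,
      "radius_in": 0.00408132539788261,
      "radius_out": 0.00367319285809435,
      "beta_in": 623.662072144722,
      "beta_out": 561.29586493025,
      "generation": 1
    },
    {
      "id": "renal_l",
      "parent": "abdominal_b",
      "length": 0.0303728917431831,
      "radius_in": 0.00274080097074062,
      "radius_out": 0.00246672087366655,
      "beta_in": 371.259161046505,
      "beta_out": 334.133244941855,
      "generation": 1
    },
    {
      "id": "renal_r",
      "parent": "abdominal_c",
      "length": 0.0331407536590099,
      "radius_in": 0.00258207200778276,
      "radius_out": 0.00232386480700448,
      "beta_in": 469.022939300153,
      "beta_out": 422.120645370138,
      "generation": 1
    },
    {
      "id": "mesenteric_inf",
      "parent": "abdominal_d",
      "length": 0.0505757066458464,
      "radius_in": 0.00167666580855846,
      "radius_out": 0.00150899922770262,
      "beta_in": 267.218344448836,
      "beta_out": 240.496510003952,
      "generation": 1
    },
    {
      "id": "iliac_common_r",
      "parent": "abdominal_e",
      "length": 0.0583715379180759,
      "radius_in": 0.0036301102922596,
      "radius_out": 0.00326709926303364,
      "beta_in": 551.28858047418,
      "beta_out": 496.159722426762,
      "generation": 1
    },
    {
      "id": "iliac_common_l",
      "parent": "abdominal_e",
      "length": 0.0569517350908369,
      "radius_in": 0.00393589792263508,
      "radius_out": 0.00354230813037157,
      "beta_in": 613.756755846991,
      "beta_out": 552.381080262292,
      "generation": 1
    }
  ],
  "terminals": [
    {
      "segment": "intercostals",
      "r1": 261698928.862658,
      "r2": 1498760121.33732,
      "c": 1.34934040498384e-09,
      "p_out": 0
    },
    {
      "segment": "mesenteric_sup",
      "r1": 158718994.727068,
      "r2": 843239663.632894,
      "c": 2.37081491130835e-09,
      "p_out": 0
    },
    {
      "segment": "renal_l",
      "r1": 331361565.095394,
      "r2": 1890398965.32533,
      "c": 1.06917847141e-09,
      "p_out": 0
    },
    {
      "segment": "renal_r",
      "r1": 432348005.802462,
      "r2": 2070967255.86273,
      "c": 9.48925037182157e-10,
      "p_out": 0
    },
    {
      "segment": "mesenteric_inf",
      "r1": 960448662.93435,
      "r2": 4976444449.90045,
      "c": 4.00118122830756e-10,
      "p_out": 0
    },
    {
      "segment": "carotid_l",
      "r1": 166596862.278916,
      "r2": 1086428380.81131,
      "c": 1.70111857528157e-09,
      "p_out": 0
    },
    {
      "segment": "celiac_a",
      "r1": 171169566.851049,
      "r2": 1308115171.6716,
      "c": 1.15502781745877e-09,
      "p_out": 0
    },
    {
      "segment": "subclavian_l_a",
      "r1": 117319231.224147,
      "r2": 1585227558.05082,
      "c": 1.23169731924726e-09,
      "p_out": 0
    },
    {
      "segment": "iliac_common_r",
      "r1": 200007941.283996,
      "r2": 1337153609.40486,
      "c": 1.4103315157891e-09,
      "p_out": 0
    },
    {
      "segment": "iliac_common_l",
      "r1": 172403416.72958,
      "r2": 1255572402.40382,
      "c": 1.4510029829809e-09,
      "p_out": 0
    },
    {
      "segment": "innominate",
      "r1": 60077401.8730644,
      "r2": 749405571.072104,
      "c": 2.62315530433127e-09,
      "p_out": 0
    }
  ]
}
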