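{
  "description": "Fixed TEAC regression equations (1- to 8-variable GA-MLR models fitted on normalized descriptors). Coefficients are in mM of TEAC per unit of min-max-normalized descriptor; 'uncertainty' is the printed +/- value, read as one standard error.",
  "models": [
    {
      "model_id": 1,
      "terms": [
        {"descriptor": "C-018", "coefficient": 0.1739, "uncertainty": 0.0687}
      ],
      "intercept": 0.0500,
      "intercept_uncertainty": 0.0156
    },
    {
      "model_id": 2,
      "terms": [
        {"descriptor": "C-018", "coefficient": 0.1760, "uncertainty": 0.0595},
        {"descriptor": "H7s", "coefficient": 0.1487, "uncertainty": 0.0673}
      ],
      "intercept": 0.0287,
      "intercept_uncertainty": 0.0166
    },
    {
      "model_id": 3,
      "terms": [
        {"descriptor": "C-018", "coefficient": 0.1835, "uncertainty": 0.0529},
        {"descriptor": "CATS2D_06_AL", "coefficient": 0.1464, "uncertainty": 0.0580},
        {"descriptor": "Mor24e", "coefficient": -0.1050, "uncertainty": 0.0487}
      ],
      "intercept": 0.0458,
      "intercept_uncertainty": 0.0157
    },
    {
      "model_id": 4,
      "terms": [
        {"descriptor": "Mor16e", "coefficient": -0.0851, "uncertainty": 0.0533},
        {"descriptor": "RDF145p", "coefficient": -0.1511, "uncertainty": 0.0964},
        {"descriptor": "C-018", "coefficient": 0.1489, "uncertainty": 0.0526},
        {"descriptor": "CATS2D_06_AL", "coefficient": 0.1991, "uncertainty": 0.0694}
      ],
      "intercept": 0.0396,
      "intercept_uncertainty": 0.0156
    },
    {
      "model_id": 5,
      "terms": [
        {"descriptor": "RCI", "coefficient": -0.1657, "uncertainty": 0.0819},
        {"descriptor": "RDF145p", "coefficient": -0.1458, "uncertainty": 0.0848},
        {"descriptor": "Mor16e", "coefficient": -0.0847, "uncertainty": 0.0469},
        {"descriptor": "C-018", "coefficient": 0.1484, "uncertainty": 0.0463},
        {"descriptor": "CATS2D_06_AL", "coefficient": 0.2113, "uncertainty": 0.0613}
      ],
      "intercept": 0.1292,
      "intercept_uncertainty": 0.0463
    },
    {
      "model_id": 6,
      "terms": [
        {"descriptor": "RCI", "coefficient": -0.1686, "uncertainty": 0.0768},
        {"descriptor": "RDF145p", "coefficient": -0.1695, "uncertainty": 0.0811},
        {"descriptor": "Mor16e", "coefficient": -0.0801, "uncertainty": 0.0456},
        {"descriptor": "H7s", "coefficient": 0.1388, "uncertainty": 0.0788},
        {"descriptor": "C-018", "coefficient": 0.1579, "uncertainty": 0.0435},
        {"descriptor": "CATS2D_04_AL", "coefficient": 0.1061, "uncertainty": 0.0712}
      ],
      "intercept": 0.1175,
      "intercept_uncertainty": 0.0439
    },
    {
      "model_id": 7,
      "terms": [
        {"descriptor": "RCI", "coefficient": -0.1700, "uncertainty": 0.0728},
        {"descriptor": "RDF145p", "coefficient": -0.1717, "uncertainty": 0.0764},
        {"descriptor": "Mor16u", "coefficient": -0.0965, "uncertainty": 0.0481},
        {"descriptor": "H7s", "coefficient": 0.1412, "uncertainty": 0.0745},
        {"descriptor": "C-018", "coefficient": 0.2087, "uncertainty": 0.0625},
        {"descriptor": "CATS2D_04_AL", "coefficient": 0.1086, "uncertainty": 0.0682},
        {"descriptor": "F03[N-F]", "coefficient": -0.1046, "uncertainty": 0.0952}
      ],
      "intercept": 0.1194,
      "intercept_uncertainty": 0.0416
    },
    {
      "model_id": 8,
      "terms": [
        {"descriptor": "RCI", "coefficient": -0.1880, "uncertainty": 0.0673},
        {"descriptor": "RDF145p", "coefficient": -0.1821, "uncertainty": 0.0703},
        {"descriptor": "Mor16u", "coefficient": -0.0861, "uncertainty": 0.0442},
        {"descriptor": "H7s", "coefficient": 0.0811, "uncertainty": 0.0753},
        {"descriptor": "nR=Ct", "coefficient": 0.0606, "uncertainty": 0.0386},
        {"descriptor": "C-018", "coefficient": 0.1483, "uncertainty": 0.0383},
        {"descriptor": "CATS2D_04_AL", "coefficient": 0.1236, "uncertainty": 0.0622},
        {"descriptor": "F06[N-F]", "coefficient": 0.0764, "uncertainty": 0.0529}
      ],
      "intercept": 0.1241,
      "intercept_uncertainty": 0.0384
    }
  ]
}
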