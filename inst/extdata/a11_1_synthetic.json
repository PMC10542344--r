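{
  "name": "A_11.1_synthetic",
  "template": "TFALEVTRHEFQYVRDKEFPFYCIDALMRIEEVPFECVDTVGGCYDCGLIFATHEPLKNYKMDSFQFCVTVFQIIEEHLVPWSTNKMSIGAPQFKSMLLAWTQQRGRMFSTTVCGGGYRCLNKACCMQCCLFLTTFDQQAFDPMYTYEYMTKTPTYATACISDFPNAWFRGSLHKKDVRRYSAGMKYPFMRCGAQSTMVCLEYRHTFYVKMGLKWKMWELTNGRKLVHQNW",
  "positions": [
    {
      "position": 105,
      "allowed": "RL"
    },
    {
      "position": 106,
      "allowed": "GF"
    },
    {
      "position": 107,
      "allowed": "RC"
    },
    {
      "position": 108,
      "allowed": "MD"
    },
    {
      "position": 109,
      "allowed": "FC"
    },
    {
      "position": 110,
      "allowed": "SQ"
    },
    {
      "position": 148,
      "allowed": "ET"
    },
    {
      "position": 149,
      "allowed": "YE"
    },
    {
      "position": 150,
      "allowed": "MG"
    },
    {
      "position": 176,
      "allowed": "KN"
    },
    {
      "position": 177,
      "allowed": "DA"
    },
    {
      "position": 215,
      "allowed": "WQ"
    },
    {
      "position": 216,
      "allowed": "KA"
    },
    {
      "position": 217,
      "allowed": "ME"
    },
    {
      "position": 218,
      "allowed": "WP"
    },
    {
      "position": 219,
      "allowed": "EH"
    }
  ],
  "insertions": [
    {
      "after": 110,
      "residues": "G",
      "optional": true
    }
  ]
}
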