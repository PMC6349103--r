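{
  "comment": "Reference diterpene carbon skeletons with standard position numbering. Atom k is skeleton position k; edges are position pairs; all bonds single. Decalin core (positions 1-10) is shared; side chains and methyls follow the field's numbering (17-20 methyl carbons, 11-16 side chain / ring C-D carbons).",
  "skeletons": [
    {
      "reference_name": "Sk1 kaurane",
      "carbons": 20,
      "edges": [[1,2],[2,3],[3,4],[4,5],[5,10],[1,10],
                [5,6],[6,7],[7,8],[8,9],[9,10],
                [8,14],[13,14],[12,13],[11,12],[9,11],
                [8,15],[15,16],[13,16],
                [4,18],[4,19],[10,20],[16,17]]
    },
    {
      "reference_name": "Sk2 clerodane",
      "carbons": 20,
      "edges": [[1,2],[2,3],[3,4],[4,5],[5,10],[1,10],
                [5,6],[6,7],[7,8],[8,9],[9,10],
                [8,17],[4,18],[5,19],[9,20],
                [9,11],[11,12],[12,13],[13,14],[14,15],[13,16]]
    },
    {
      "reference_name": "Sk3 abietane",
      "carbons": 20,
      "edges": [[1,2],[2,3],[3,4],[4,5],[5,10],[1,10],
                [5,6],[6,7],[7,8],[8,9],[9,10],
                [8,14],[13,14],[12,13],[11,12],[9,11],
                [13,15],[15,16],[15,17],
                [4,18],[4,19],[10,20]]
    },
    {
      "reference_name": "Sk4 labdane",
      "carbons": 20,
      "edges": [[1,2],[2,3],[3,4],[4,5],[5,10],[1,10],
                [5,6],[6,7],[7,8],[8,9],[9,10],
                [8,17],[4,18],[4,19],[10,20],
                [9,11],[11,12],[12,13],[13,14],[14,15],[13,16]]
    },
    {
      "reference_name": "Sk6 pimarane",
      "carbons": 20,
      "edges": [[1,2],[2,3],[3,4],[4,5],[5,10],[1,10],
                [5,6],[6,7],[7,8],[8,9],[9,10],
                [8,14],[13,14],[12,13],[11,12],[9,11],
                [13,15],[15,16],[13,17],
                [4,18],[4,19],[10,20]]
    },
    {
      "reference_name": "Sk14 atisane",
      "carbons": 20,
      "edges": [[1,2],[2,3],[3,4],[4,5],[5,10],[1,10],
                [5,6],[6,7],[7,8],[8,9],[9,10],
                [8,14],[13,14],[12,13],[11,12],[9,11],
                [8,15],[15,16],[12,16],
                [4,18],[4,19],[10,20],[16,17]]
    }
  ]
}
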