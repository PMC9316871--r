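{
  "description": "Names, definitions and families of the molecular descriptors appearing in the eight fixed TEAC models. 'models' lists the model sizes (number of variables) whose equation uses the descriptor.",
  "descriptors": [
    {"name": "C-018", "models": [1, 2, 3, 4, 5, 6, 7, 8], "definition": "=CHX", "family": "Atom-centred fragments"},
    {"name": "H7s", "models": [2, 6, 7, 8], "definition": "H autocorrelation of lag 7/weighted by I-state", "family": "GETAWAY descriptors"},
    {"name": "CATS2D_06_AL", "models": [3, 4, 5], "definition": "CATS2D Acceptor-Lipophilic at lag 06", "family": "CATS 2D"},
    {"name": "Mor24e", "models": [3], "definition": "signal 24/weighted by Sanderson electronegativity", "family": "3D-MoRSE descriptors"},
    {"name": "Mor16e", "models": [4, 5, 6], "definition": "signal 16/weighted by Sanderson electronegativity", "family": "3D-MoRSE descriptors"},
    {"name": "RDF145p", "models": [4, 5, 6, 7, 8], "definition": "Radial Distribution Function-145/weighted by polarizability", "family": "RDF descriptors"},
    {"name": "RCI", "models": [5, 6, 7, 8], "definition": "ring complexity index", "family": "Ring descriptors"},
    {"name": "CATS2D_04_AL", "models": [6, 7, 8], "definition": "CATS2D Acceptor-Lipophilic at lag 04", "family": "CATS 2D"},
    {"name": "Mor16u", "models": [7, 8], "definition": "signal 16/unweighted", "family": "3D-MoRSE descriptors"},
    {"name": "F03[N-F]", "models": [7], "definition": "Frequency of N-F at topological distance 3", "family": "2D Atom Pairs"},
    {"name": "nR=Ct", "models": [8], "definition": "number of aliphatic tertiary C(sp2)", "family": "Functional group counts"},
    {"name": "F06[N-S]", "models": [8], "definition": "Frequency of N-S at topological distance 6", "family": "2D Atom Pairs", "note": "The source metadata lists this descriptor for the eight-variable model while the printed equation spells the term F06[N-F]; both spellings are retained and resolve to this entry."},
    {"name": "F06[N-F]", "models": [8], "definition": "Frequency of N-S at topological distance 6", "family": "2D Atom Pairs", "note": "Equation spelling of the eight-variable-model term whose metadata entry reads F06[N-S]; the discrepancy is recorded rather than resolved."}
  ]
}
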