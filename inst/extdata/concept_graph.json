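{
  "comment": "Radiology finding concept graph over the 14 label nodes. Edges follow the CheXpert-style clinical hierarchy: the parent finding 'lung opacity' connects to its child opacities, pneumonia is a form of consolidation, cardiomegaly relates to an enlarged cardiomediastinum, and the pleural findings are grouped. Edit or replace this file to supply a different expert-defined graph.",
  "nodes": [
    "atelectasis", "cardiomegaly", "consolidation", "edema",
    "enlarged_cardiomediastinum", "fracture", "lung_lesion", "lung_opacity",
    "pleural_effusion", "pleural_other", "pneumonia", "pneumothorax",
    "support_devices", "normal"
  ],
  "edges": [
    ["lung_opacity", "edema"],
    ["lung_opacity", "consolidation"],
    ["lung_opacity", "pneumonia"],
    ["lung_opacity", "lung_lesion"],
    ["lung_opacity", "atelectasis"],
    ["consolidation", "pneumonia"],
    ["enlarged_cardiomediastinum", "cardiomegaly"],
    ["pleural_effusion", "pleural_other"]
  ]
}
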