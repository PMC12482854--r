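{
  "version": "1.0",
  "comment": "Composite region definitions by structure name against the bundled label dictionary. 'whole_cerebellum' (cerebellar GM + WM) is the amyloid reference; 'cerebellar_gm' is the tau reference. 'centaur_metatemporal' is the meta-temporal tau target mask. 'centiloid_cortical' is the package-default amyloid target mask and is meant to be overridden or re-derived per cohort with select_discriminative_structures().",
  "masks": {
    "whole_cerebellum": [
      "Left Cerebellum Exterior", "Right Cerebellum Exterior",
      "Left Cerebellum White Matter", "Right Cerebellum White Matter",
      "Cerebellar Vermal Lobules I-V", "Cerebellar Vermal Lobules VI-VII",
      "Cerebellar Vermal Lobules VIII-X"
    ],
    "cerebellar_gm": [
      "Left Cerebellum Exterior", "Right Cerebellum Exterior",
      "Cerebellar Vermal Lobules I-V", "Cerebellar Vermal Lobules VI-VII",
      "Cerebellar Vermal Lobules VIII-X"
    ],
    "centaur_metatemporal": [
      "Left Ent entorhinal area", "Right Ent entorhinal area",
      "Left Amygdala", "Right Amygdala",
      "Left PHG parahippocampal gyrus", "Right PHG parahippocampal gyrus",
      "Left FuG fusiform gyrus", "Right FuG fusiform gyrus",
      "Left ITG inferior temporal gyrus", "Right ITG inferior temporal gyrus",
      "Left MTG middle temporal gyrus", "Right MTG middle temporal gyrus",
      "Left TMP temporal pole", "Right TMP temporal pole"
    ],
    "centiloid_cortical": [
      "Left ACgG anterior cingulate gyrus", "Right ACgG anterior cingulate gyrus",
      "Left MCgG middle cingulate gyrus", "Right MCgG middle cingulate gyrus",
      "Left PCgG posterior cingulate gyrus", "Right PCgG posterior cingulate gyrus",
      "Left SFG superior frontal gyrus", "Right SFG superior frontal gyrus",
      "Left MSFG superior frontal gyrus medial segment", "Right MSFG superior frontal gyrus medial segment",
      "Left MFG middle frontal gyrus", "Right MFG middle frontal gyrus",
      "Left OpIFG opercular part of the inferior frontal gyrus", "Right OpIFG opercular part of the inferior frontal gyrus",
      "Left TrIFG triangular part of the inferior frontal gyrus", "Right TrIFG triangular part of the inferior frontal gyrus",
      "Left OrIFG orbital part of the inferior frontal gyrus", "Right OrIFG orbital part of the inferior frontal gyrus",
      "Left AnG angular gyrus", "Right AnG angular gyrus",
      "Left SMG supramarginal gyrus", "Right SMG supramarginal gyrus",
      "Left SPL superior parietal lobule", "Right SPL superior parietal lobule",
      "Left PCu precuneus", "Right PCu precuneus",
      "Left STG superior temporal gyrus", "Right STG superior temporal gyrus",
      "Left MTG middle temporal gyrus", "Right MTG middle temporal gyrus",
      "Left ITG inferior temporal gyrus", "Right ITG inferior temporal gyrus"
    ]
  }
}
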