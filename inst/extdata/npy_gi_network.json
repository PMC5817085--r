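{
  "name": "Gi-only beta-cell network, NPY acting on the Y1 receptor",
  "ligand": "NPY",
  "description": "NPY binding to Y1 activates Gi only: adenylyl cyclase is inhibited saturably, cAMP falls, PKA and Epac activity fall, and insulin secretion - driven at baseline mostly by the cAMP arm plus a small basal release - drops below the ligand-free baseline. No Gq branch is wired, matching the Gi coupling of this receptor. Rate constants follow the same conventions as the GPR142 fixtures.",
  "species": [
    {"name": "NPY", "init_um": 1.0, "compartment": "extracellular"},
    {"name": "Y1R", "init_um": 0.1, "compartment": "membrane"},
    {"name": "Y1R_complex", "init_um": 0.0, "compartment": "membrane"},
    {"name": "Gi", "init_um": 1.0, "compartment": "cell"},
    {"name": "Gi_active", "init_um": 0.0, "compartment": "cell"},
    {"name": "ATP", "init_um": 1000.0, "compartment": "cell"},
    {"name": "cAMP", "init_um": 0.0, "compartment": "cell"},
    {"name": "AMP", "init_um": 0.0, "compartment": "cell"},
    {"name": "PKA", "init_um": 1.0, "compartment": "cell"},
    {"name": "PKA_active", "init_um": 0.0, "compartment": "cell"},
    {"name": "Epac", "init_um": 1.0, "compartment": "cell"},
    {"name": "Epac_active", "init_um": 0.0, "compartment": "cell"},
    {"name": "Insulin_granule", "init_um": 10.0, "compartment": "cell"},
    {"name": "Insulin_secreted", "init_um": 0.0, "compartment": "extracellular"}
  ],
  "reactions": [
    {"id": "r_bind", "comment": "NPY-Y1 association, k_on 10 /uM/s",
     "reactants": ["NPY", "Y1R"], "products": ["Y1R_complex"],
     "law": {"type": "mass_action", "params": {"k": 10.0}}},
    {"id": "r_unbind", "comment": "complex dissociation, k_off 0.01 /s",
     "reactants": ["Y1R_complex"], "products": ["NPY", "Y1R"],
     "law": {"type": "mass_action", "params": {"k": 0.01}}},
    {"id": "r_gi_act", "comment": "complex-catalyzed Gi activation",
     "reactants": ["Gi"], "products": ["Gi_active"],
     "modifiers": ["Y1R_complex"],
     "law": {"type": "mass_action", "params": {"k": 5.0}}},
    {"id": "r_gi_deact", "comment": "Gi deactivation, first order",
     "reactants": ["Gi_active"], "products": ["Gi"],
     "law": {"type": "mass_action", "params": {"k": 0.1}}},
    {"id": "r_ac", "comment": "adenylyl cyclase ATP -> cAMP, Gi-inhibited (Ki 0.05 uM)",
     "reactants": ["ATP"], "products": ["cAMP"],
     "inhibitors": [{"species": "Gi_active", "Ki": 0.05}],
     "law": {"type": "michaelis_menten", "params": {"Vm": 0.01, "Km": 500.0}}},
    {"id": "r_pde", "comment": "phosphodiesterase cAMP -> AMP, first order",
     "reactants": ["cAMP"], "products": ["AMP"],
     "law": {"type": "mass_action", "params": {"k": 0.2}}},
    {"id": "r_pka_act", "comment": "cAMP-driven PKA activation",
     "reactants": ["PKA"], "products": ["PKA_active"],
     "modifiers": ["cAMP"],
     "law": {"type": "mass_action", "params": {"k": 1.0}}},
    {"id": "r_pka_deact", "comment": "PKA deactivation, first order",
     "reactants": ["PKA_active"], "products": ["PKA"],
     "law": {"type": "mass_action", "params": {"k": 0.2}}},
    {"id": "r_epac_act", "comment": "cAMP-driven Epac activation",
     "reactants": ["Epac"], "products": ["Epac_active"],
     "modifiers": ["cAMP"],
     "law": {"type": "mass_action", "params": {"k": 1.0}}},
    {"id": "r_epac_deact", "comment": "Epac deactivation, first order",
     "reactants": ["Epac_active"], "products": ["Epac"],
     "law": {"type": "mass_action", "params": {"k": 0.2}}},
    {"id": "r_secr_basal", "comment": "small basal granule release",
     "reactants": ["Insulin_granule"], "products": ["Insulin_secreted"],
     "law": {"type": "mass_action", "params": {"k": 0.0001}}},
    {"id": "r_secr_pka", "comment": "PKA-driven release, the dominant baseline drive",
     "reactants": ["Insulin_granule"], "products": ["Insulin_secreted"],
     "modifiers": ["PKA_active"],
     "law": {"type": "mass_action", "params": {"k": 0.002}}},
    {"id": "r_secr_epac", "comment": "Epac-driven release",
     "reactants": ["Insulin_granule"], "products": ["Insulin_secreted"],
     "modifiers": ["Epac_active"],
     "law": {"type": "mass_action", "params": {"k": 0.002}}}
  ],
  "readouts": ["Insulin_secreted", "cAMP"],
  "conserved_moieties": [
    {"name": "receptor_total", "species": ["Y1R", "Y1R_complex"]},
    {"name": "ligand_total", "species": ["NPY", "Y1R_complex"]},
    {"name": "Gi_total", "species": ["Gi", "Gi_active"]},
    {"name": "PKA_total", "species": ["PKA", "PKA_active"]},
    {"name": "Epac_total", "species": ["Epac", "Epac_active"]},
    {"name": "insulin_total", "species": ["Insulin_granule", "Insulin_secreted"]}
  ]
}
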