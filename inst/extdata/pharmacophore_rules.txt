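# Default pharmacophore typing rules.
# pattern  label  [atoms]
# '@'-prefixed patterns are builtin attribute predicates; other patterns
# are substructure patterns whose matched atoms receive the label.
@aromatic        Aromatic
@hbond_donor     Donor
@hbond_acceptor  Acceptor
@hydrophobic     Hydrophobic
@pos_charge      PosIonizable
@aliphatic_amine PosIonizable
@neg_charge      NegIonizable
@acid_group      NegIonizable
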