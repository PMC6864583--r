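{
  "version": "1.0",
  "tables": {
    "E":   {"units": "Pauling units", "source": "Pauling electronegativity scale"},
    "M":   {"units": "Da", "source": "IUPAC standard atomic weights (abridged)"},
    "POL": {"units": "A^3", "source": "published static atomic dipole polarizabilities"},
    "R":   {"units": "cm^3/mol", "source": "classical atomic refraction increments"},
    "VDW": {"units": "A^3", "source": "4/3*pi*r^3 over Bondi van der Waals radii"},
    "PSA": {"units": "A^2", "source": "Ertl-style fragment contributions reduced to element+environment classes"},
    "HYD": {"units": "logP contribution", "source": "Ghose-Crippen-style atomic logP reduced to element+environment classes; attached hydrogens add the H row"}
  },
  "notes": "CHR (partial charge) is computed, not table-driven; see gasteiger_charges()."
}
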