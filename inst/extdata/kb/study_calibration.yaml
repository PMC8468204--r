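# Study-cohort calibration for the synthetic-cohort generator.
#
# All counts are patient counts out of n_patients. Disease labels use the
# indication-matrix vocabulary; coarse registry sites are refined to that
# granularity so that both the demographic mix and the per-disease
# denominators of the risk matrix are matched simultaneously.
n_patients: 291
disease_mix:
  "Colon/rectal": 55
  "Ovary": 25
  "Cervix": 1
  "Uterus": 22
  "Vulva": 1
  "Head and neck": 36
  "Brain": 25
  "Pancreas": 16
  "Acute lymphoblastic leukemia": 3
  "Leukemia/lymphoma other": 12
  "Gastric/gastroesophageal": 15
  "Bladder": 3
  "Kidney": 11
  "Lung": 14
  "Small bowel adenocarcinoma": 2
  "Carcinoid/neuroendocrine": 10
  "Basal cell skin": 1
  "Squamous cell skin": 4
  "Skin other": 7
  "Breast": 7
  "Hepatobiliary": 7
  "Anus": 1
  "Thyroid": 4
  "Other": 9
demographics:
  gender: {Female: 147, Male: 139, "Non-Binary": 1}
  race_ethnicity: {"Non-Hispanic White": 277, "Non-Hispanic Black": 14}
  stage: {I: 31, II: 42, III: 93, IV: 78, "N/A": 47}
  age: {median: 61, iqr_low: 52, iqr_high: 68}
# per (gene, allele) patient-level genotype counts (hom / het); draws are
# independent across alleles and genes, with at most two variant allele
# copies per gene enforced by rejection
genotype_model:
  UGT1A1: {"*28": {hom: 23, het: 134}}
  DPYD:
    "c.2846A>T": {hom: 0, het: 1}
    "*2A": {hom: 0, het: 4}
    "HapB3": {hom: 0, het: 7}
    "c.557A>G": {hom: 0, het: 1}
    "*7": {hom: 0, het: 1}
  TPMT:
    "*3A": {hom: 2, het: 31}
    "*3B": {hom: 0, het: 1}
    "*3C": {hom: 1, het: 3}
    "*2": {hom: 0, het: 2}
  CYP2D6: {"*6": {hom: 0, het: 5}}
  CYP2C9:
    "*3": {hom: 0, het: 37}
    "*11": {hom: 0, het: 2}
  CYP3A5:
    "*6": {hom: 0, het: 3}
    "*7": {hom: 0, het: 2}
  G6PD: {"A-202A_376G-III": {hom: 0, het: 1}}
  CYP4F2: {"*3": {hom: 21, het: 111}}
  SLCO1B1:
    "*15 or *17": {hom: 5, het: 59}
    "*5": {hom: 2, het: 10}
  VKORC1: {"1173C>T": {hom: 11, het: 60}}
  RYR1:
    "c.7042_7044delGAG": {hom: 0, het: 1}
    "c.14818G>A": {hom: 0, het: 1}
  CFTR: {"c.1652G>A": {hom: 0, het: 0}}
  CYP2C19: {"*7": {hom: 0, het: 0}}
  CACNA1S:
    "c.520C>T": {hom: 0, het: 0}
    "c.3257G>A": {hom: 0, het: 0}
  HLA-B:
    "*57:01": {hom: 0, het: 0}
    "*15:02": {hom: 0, het: 0}
    "*58:01": {hom: 0, het: 0}
# published per-gene totals as printed, with an internal-consistency flag
# (TPMT total frequency and the SLCO1B1 total carrier row do not
# reproduce from their own genotype-count rows; stored verbatim, never
# used as generator input)
printed_gene_totals:
  UGT1A1: {n_carriers: 157, frequency: 0.3093, consistent: true}
  DPYD: {n_carriers: 14, frequency: 0.0240, consistent: true}
  TPMT: {n_carriers: 40, frequency: 0.0775, consistent: false}
  CYP2C9: {n_carriers: 39, frequency: 0.0670, consistent: true}
  CYP3A5: {n_carriers: 5, frequency: 0.0086, consistent: true}
  CYP4F2: {n_carriers: 132, frequency: 0.2629, consistent: true}
  SLCO1B1: {n_carriers: 12, frequency: 0.1427, consistent: false}
  VKORC1: {n_carriers: 71, frequency: 0.1409, consistent: true}
  RYR1: {n_carriers: 2, frequency: 0.0034, consistent: true}
  Any: {n_carriers: 263, frequency: ~, consistent: true}
# per-(drug, tier) probability that a patient with a matching indication
# receives the drug; rough exposure calibration giving ~16% of patients a
# genotype-relevant anti-cancer drug
treatment_model:
  exposure:
    irinotecan: {preferred: 0.15, other: 0.02}
    fluorouracil: {preferred: 0.25, other: 0.02}
    capecitabine: {preferred: 0.05, other: 0.02}
    mercaptopurine: {preferred: 0.34, other: 0.02}
    thioguanine: {preferred: 0.00, other: 0.00}
    tamoxifen: {preferred: 0.15, other: 0.02}
  treated_elsewhere: 0.10
toxicity_model:
  variant_rate: 0.7777778      # 7/9 for non-normal metabolizers
  normal_rate: 0.3611111       # 13/36 for normal metabolizers
  nuisance_event_rate: 0.10    # fatigue / allergic reaction, to exercise exclusions
  death_given_toxicity: 0.02
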