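# Attribute schemas for the bundled synthetic oncology corpus.
site:
  labels: ["NULL", LUNG, BREAST, COLON, PROSTATE, PANCREAS, LIVER, KIDNEY,
           BLADDER, STOMACH, OVARY, ESOPHAGUS, THYROID]
  lexicon:
    LUNG: [lung, right lung, left lung, pulmonary, right upper lobe]
    BREAST: [breast, left breast, right breast, mammary]
    COLON: [colon, sigmoid colon, ascending colon, colonic]
    PROSTATE: [prostate, prostatic]
    PANCREAS: [pancreas, pancreatic, pancreatic head]
    LIVER: [liver, hepatic, hepatic lobe]
    KIDNEY: [kidney, renal, left kidney, right kidney]
    BLADDER: [bladder, urinary bladder]
    STOMACH: [stomach, gastric, gastric antrum]
    OVARY: [ovary, left ovary, right ovary, ovarian]
    ESOPHAGUS: [esophagus, esophageal, distal esophagus]
    THYROID: [thyroid, thyroid gland]
histology:
  labels: ["NULL", ADENOCARCINOMA, SQUAMOUS, DUCTAL, SMALL_CELL,
           TRANSITIONAL, PAPILLARY, HEPATOCELLULAR, CLEAR_CELL]
  lexicon:
    ADENOCARCINOMA: [adenocarcinoma, invasive adenocarcinoma]
    SQUAMOUS: [squamous cell carcinoma, squamous carcinoma]
    DUCTAL: [ductal carcinoma, invasive ductal carcinoma]
    SMALL_CELL: [small cell carcinoma]
    TRANSITIONAL: [transitional cell carcinoma, urothelial carcinoma]
    PAPILLARY: [papillary carcinoma]
    HEPATOCELLULAR: [hepatocellular carcinoma]
    CLEAR_CELL: [clear cell carcinoma]
clinical_T:
  labels: ["NULL", "0", "1", "2", "3", "4", "is"]
  lexicon:
    "0": [ct0, stage t0, t0]
    "1": [ct1, stage t1, t1]
    "2": [ct2, stage t2, t2]
    "3": [ct3, stage t3, t3]
    "4": [ct4, stage t4, t4]
    "is": [tis, carcinoma in situ, in situ]
clinical_N:
  labels: ["NULL", "0", "1+"]
  lexicon:
    "0": [cn0, n0, no nodal involvement, no enlarged lymph nodes]
    "1+": [cn1, n1, nodal involvement, enlarged regional lymph nodes]
clinical_M:
  labels: ["NULL", "0", "1"]
  lexicon:
    "0": [cm0, m0, no evidence of distant metastasis]
    "1": [cm1, m1, distant metastasis, metastatic disease]
pathologic_T:
  labels: ["NULL", "0", "1", "2", "3", "4", "is"]
  lexicon:
    "0": [pt0, pathologic stage t0]
    "1": [pt1, pathologic stage t1]
    "2": [pt2, pathologic stage t2]
    "3": [pt3, pathologic stage t3]
    "4": [pt4, pathologic stage t4]
    "is": [ptis, pathologic carcinoma in situ]
pathologic_N:
  labels: ["NULL", "0", "1+"]
  lexicon:
    "0": [pn0, nodes negative for tumor, lymph nodes negative]
    "1+": [pn1, nodes positive for tumor, lymph node metastasis]
pathologic_M:
  labels: ["NULL", "0", "1"]
  lexicon:
    "0": [pm0, no distant spread identified]
    "1": [pm1, distant metastasis confirmed]
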