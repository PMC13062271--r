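# Default keyword dictionary for tissue annotation. Matching is
# case-insensitive substring matching over the concatenated free-text
# annotation (cancer type, disease, cell line). Keywords mix cancer-type
# terms with widely used cell-line names for each tissue.
Blood:
  [leukemia, leukaemia, lymphoma, myeloma, blood, hematolog, haematolog,
   jurkat, hl-60, hl60, k562, k-562, u937, u-937, thp-1, ccrf-cem, molt-4,
   kg-1, raji]
Brain:
  [brain, glioma, glioblastoma, neuroblastoma, astrocytoma, medulloblastoma,
   u87, u-87, u251, u-251, sh-sy5y, t98g, c6 glioma, ln-229]
Breast:
  [breast, mammary, mcf-7, mcf7, mda-mb, t47d, t-47d, sk-br-3, skbr3, bt-474,
   4t1, zr-75]
Cervix:
  [cervix, cervical, hela, siha, caski, c33a, c-33a, me-180]
Colon:
  [colon, colorectal, rectal, ht-29, ht29, hct116, hct-116, hct-8, caco-2,
   caco2, sw480, sw-480, sw620, sw-620, dld-1, lovo, colo205, colo-205]
Liver:
  [liver, hepatocellular, hepatoma, hepatic, hepg2, hep g2, hep-g2, huh-7,
   huh7, smmc-7721, bel-7402, sk-hep, plc/prf]
Lung:
  [lung, a549, a-549, nci-h460, nci-h1299, h1299, h-1299, nci-h23, llc,
   lewis lung, 95d, 95-d, calu]
Prostate:
  [prostate, pc-3, pc3, du145, du-145, lncap, 22rv1, tramp-c1]
Skin:
  [skin, melanoma, a375, a-375, b16, sk-mel, mel-juso, wm-115, squamous cell
   carcinoma of the skin]
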