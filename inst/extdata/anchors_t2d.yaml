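# Type 2 diabetes complication categories and their expert anchor codes.
# Category order defines the complication index (1..12); each ICD-10 code
# may anchor at most one category.
complications:
  - name: "Diabetes"
    codes: ["E11.9"]
  - name: "Acute complications"
    codes: ["E11.0", "E11.1", "K81", "J20"]
  - name: "Cardiovascular"
    codes: ["I25", "I10"]
  - name: "Nephropathy"
    codes: ["E11.2", "N18"]
  - name: "Ophthalmopathy"
    codes: ["E11.3", "H26.9"]
  - name: "Peripheral vascular"
    codes: ["E11.5", "I83"]
  - name: "Cerebrovascular"
    codes: ["I63", "G45"]
  - name: "Neuropathy"
    codes: ["E11.4", "G63.2"]
  - name: "Metabolic complications"
    codes: ["E11.6", "E78"]
  - name: "Tumor"
    codes: ["Z51.1", "C34", "C16"]
  - name: "Musculoskeletal"
    codes: ["M48", "M13", "M81"]
  - name: "Autoimmune diseases"
    codes: ["K52", "E04", "J45"]
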