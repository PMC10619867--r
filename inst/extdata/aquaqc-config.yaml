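activity_types:
  Field Msr/Obs: regular_field
  Sample-Routine: regular_lab
  Quality Control Sample-Field Blank: field_blank
  Quality Control Sample-Lab Blank: lab_blank
  Quality Control Sample-Field Duplicate: field_dup
  Quality Control Sample-Lab Duplicate: lab_dup
  Quality Control Sample-Lab Spike: spike
  Quality Control-Calibration Check: instrument_check
relative_depth_names:
- Surface
- Midwater
- Near Bottom
- Bottom
depth_units:
- m
- ft
depth_warn_m: 1.0
parameters:
  Parameter:
  - DO
  - Ammonia
  - TP
  - Nitrate
  - pH
  - Sp Conductance
  - E.coli
  - Water Temp
  Units:
  - mg/l
  - mg/l
  - mg/l
  - mg/l
  - s.u.
  - uS/cm
  - MPN/100ml
  - deg C
  Negative Ok:
  - no
  - no
  - no
  - no
  - no
  - no
  - no
  - yes
qualifier_attributes: []
frequency_excludes_qualified: yes
spreadsheet_rows: no
thresholds:
  Parameter:
  - DO
  - DO
  - pH
  - pH
  - E.coli
  - Water Temp
  Context:
  - fresh
  - marine
  - fresh
  - fresh
  - fresh
  - fresh
  Label:
  - Aquatic life minimum
  - Aquatic life minimum
  - Lower bound
  - Upper bound
  - Recreational criterion
  - Warmwater maximum
  Value:
  - 5.0
  - 6.0
  - 6.5
  - 8.3
  - 126.0
  - 28.3
  Unit:
  - mg/l
  - mg/l
  - s.u.
  - s.u.
  - MPN/100ml
  - deg C
  Source:
  - USEPA example criteria
  - USEPA example criteria
  - USEPA example criteria
  - USEPA example criteria
  - USEPA 2012 RWQC
  - Example state standard
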