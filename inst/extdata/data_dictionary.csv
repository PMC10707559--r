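column,type,units,allowed,required,description
id,string,,unique per cohort,yes,Opaque athlete identifier
sex,string,,male|female,yes,Biological sex
age,numeric,years,[10-60],no,Age at screening
ethnicity,string,,caucasian|black|other,no,Self-reported ethnicity
sport_category,string,,power|skills|endurance|mixed,no,Sport discipline group
height,numeric,cm,[120-230],no,Standing height
weight,numeric,kg,[30-200],no,Body weight
waist,numeric,cm,>0,no,Waist circumference
hip,numeric,cm,>0,no,Hip circumference (optional; protocol unspecified; stored for descriptive W/H ratio only)
fat_mass_pct,numeric,%,(0-60),no,Body fat percentage from bioelectric impedance
tc,numeric,mg/dL,>0,no,Total cholesterol
ldl,numeric,mg/dL,>0,yes,LDL cholesterol (missing value excludes the record from scoring)
hdl,numeric,mg/dL,>0,yes,HDL cholesterol (missing value excludes the record from scoring)
tg,numeric,mg/dL,>0,no,Triglycerides
smoker,boolean,,true|false,no,Regular smoker (at least one cigarette per day)
family_ath,boolean,,true|false,no,Family history of premature atherosclerotic disease
family_dyslipidemia,boolean,,true|false,no,First-degree relative treated for dyslipidemia
hypertension,boolean,,true|false,no,Hypertension history or treatment
diabetes,boolean,,true|false,no,Diabetes history or treatment
alcohol_user,boolean,,true|false,no,At least one alcoholic drink per week
lipid_lowering_therapy,boolean,,true|false,no,Statin/ezetimibe/nutraceutical use; flagged records are excluded from scoring and cut-off analysis
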