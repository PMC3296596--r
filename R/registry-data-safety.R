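# The 124 prescribing-safety criteria (S-001..S-124). Each predicate
# encodes the hazardous state as written: a flag means the high-risk
# pattern is present at the index date. Topic and category codes are
# stored as printed in the instrument, including its known anomalies
# (the digoxin U&E-monitoring pair filed under topic S8, the MS3 tally
# position of S-083, and the quality-domain "A" tag on S-102); see
# validate_registry().

safety_criteria <- function() {
  sc <- function(id_num, ...) {
    crit(sprintf("S-%03d", id_num), domain = "safety", ...)
  }
  lda <- low_dose_aspirin()

  # warfarin pharmacokinetic anti-infective interactions (topic S11)
  warf_ddi <- function(id, necessity, set, label) {
    sc(id, category = "MS4", necessity = necessity, topic = "S11",
       event = "Bleeding",
       text = sprintf("On warfarin: co-prescribed %s", label),
       pred = p_all(on_drug("WARFARIN"), on_drug(set)))
  }
  # digoxin dose ceiling under interacting co-prescription (topic S18)
  dig_ddi <- function(id, set, label) {
    sc(id, category = "MS5", necessity = "N", topic = "S18",
       event = "Digoxin toxicity",
       text = sprintf("On digoxin and %s: digoxin >= 250 mcg/day", label),
       pred = p_all(on_drug(set),
                    daily_dose_ge("DIGOXIN", 250, unit = "mcg/day")))
  }
  # simvastatin dose ceiling under interacting co-prescription (topic S26)
  simva_ddi <- function(id, set, label, ceiling) {
    sc(id, category = "MS5", necessity = "N", topic = "S26",
       event = "Rhabdomyolysis",
       text = sprintf("On simvastatin and %s: simvastatin > %d mg/day",
                      label, ceiling),
       pred = p_all(on_drug(set),
                    daily_dose_gt("SIMVASTATIN", ceiling)))
  }
  # DMARD full-blood-count monitoring (topic S21)
  fbc <- function(id, necessity, set, label, weeks) {
    sc(id, category = "MS8", necessity = necessity, topic = "S21",
       event = "Blood dyscrasias",
       text = sprintf("On %s: no FBC check in the last %d weeks", label,
                      weeks),
       pred = p_all(on_drug(set), no_observation_within("FBC", weeks)))
  }
  # drugs to avoid in chronic heart failure (topic S28)
  chf_avoid <- function(id, set, label) {
    sc(id, category = "MS3", necessity = "N", topic = "S28",
       event = "Heart failure exacerbation",
       text = sprintf("Chronic heart failure: prescribed %s", label),
       pred = p_all(has_condition("CHF"), on_drug(set)))
  }
  active_asthma <- p_all(has_condition("ASTHMA"),
                         issues_in_window_ge("BETA_AGONIST_INHALER", 1, 52))

  bind_rows(
    sc(1, category = "MS1", necessity = "N", topic = "S1",
       event = "GI toxicity/bleeding",
       text = "Previous peptic ulcer on low-dose aspirin: no gastroprotection",
       pred = p_all(has_condition("PEPTIC_ULCER"), lda,
                    p_not(on_drug("GIP")))),
    sc(2, category = "MS1", necessity = "N", topic = "S1",
       event = "GI toxicity/bleeding",
       text = "Age >= 65 on warfarin and low-dose aspirin: no gastroprotection",
       pred = p_all(age_ge(65), on_drug("WARFARIN"), lda,
                    p_not(on_drug("GIP")))),
    sc(3, category = "MS1", necessity = "N", topic = "S1",
       event = "GI toxicity/bleeding",
       text = "Age >= 65 on warfarin and clopidogrel: no gastroprotection",
       pred = p_all(age_ge(65), on_drug("WARFARIN"), on_drug("CLOPIDOGREL"),
                    p_not(on_drug("GIP")))),
    sc(4, category = "MS1", necessity = "N", topic = "S1",
       event = "GI toxicity/bleeding",
       text = "Age >= 65 on low-dose aspirin and clopidogrel: no gastroprotection",
       pred = p_all(age_ge(65), lda, on_drug("CLOPIDOGREL"),
                    p_not(on_drug("GIP")))),
    sc(5, category = "MS1", necessity = "I", topic = "S1",
       event = "GI toxicity/bleeding",
       text = "Age >= 75 on low-dose aspirin: no gastroprotection",
       pred = p_all(age_ge(75), lda, p_not(on_drug("GIP")))),
    sc(6, category = "MS1", necessity = "N", topic = "S1",
       event = "GI toxicity/bleeding",
       text = "Previous peptic ulcer on an oral non-selective NSAID for > 12 weeks: no gastroprotection",
       pred = p_all(has_condition("PEPTIC_ULCER"),
                    exposure_weeks_gt("NSAID_NS_ORAL", 12),
                    p_not(on_drug("GIP")))),
    sc(7, category = "MS1", necessity = "N", topic = "S1",
       event = "GI toxicity/bleeding",
       text = "Age >= 75 on an oral non-selective NSAID for > 12 weeks: no gastroprotection",
       pred = p_all(age_ge(75), exposure_weeks_gt("NSAID_NS_ORAL", 12),
                    p_not(on_drug("GIP")))),
    sc(8, category = "MS1", necessity = "I", topic = "S1",
       event = "GI toxicity/bleeding",
       text = "Age 65-74 on an oral non-selective NSAID for > 12 weeks: no gastroprotection",
       pred = p_all(age_between(65, 74),
                    exposure_weeks_gt("NSAID_NS_ORAL", 12),
                    p_not(on_drug("GIP")))),
    sc(9, category = "MS1", necessity = "N", topic = "S1",
       event = "GI toxicity/bleeding",
       text = "Age >= 65 on warfarin and an oral non-selective NSAID: no gastroprotection",
       pred = p_all(age_ge(65), on_drug("WARFARIN"),
                    on_drug("NSAID_NS_ORAL"), p_not(on_drug("GIP")))),
    sc(10, category = "MS1", necessity = "N", topic = "S1",
       event = "GI toxicity/bleeding",
       text = "Age >= 65 on low-dose aspirin and an oral non-selective NSAID for > 12 weeks: no gastroprotection",
       pred = p_all(age_ge(65), lda, exposure_weeks_gt("NSAID_NS_ORAL", 12),
                    p_not(on_drug("GIP")))),
    sc(11, category = "MS2", necessity = "N", topic = "S2",
       event = "General NSAID toxicity",
       text = "Age >= 65: oral NSAID for osteoarthritis without prior trial of full-dose paracetamol",
       pred = p_all(age_ge(65), has_condition("OSTEOARTHRITIS"),
                    on_drug("NSAID_ORAL"),
                    never_prescribed("PARACETAMOL",
                                     min_daily_dose = 3000))),
    sc(12, category = "MS2", necessity = "N", topic = "S2",
       event = "General NSAID toxicity",
       text = "Age >= 75: oral NSAID for minor trauma without prior trial of full-dose paracetamol",
       pred = p_all(age_ge(75), has_condition("MINOR_TRAUMA"),
                    on_drug("NSAID_ORAL"),
                    never_prescribed("PARACETAMOL",
                                     min_daily_dose = 3000))),
    sc(13, category = "MS2", necessity = "I", topic = "S2",
       event = "General NSAID toxicity",
       text = "Age 65-74: oral NSAID for minor trauma without prior trial of full-dose paracetamol",
       pred = p_all(age_between(65, 74), has_condition("MINOR_TRAUMA"),
                    on_drug("NSAID_ORAL"),
                    never_prescribed("PARACETAMOL",
                                     min_daily_dose = 3000))),
    sc(14, category = "MS3", necessity = "N", topic = "S3",
       event = "Renal toxicity",
       text = "CKD stage 3: prescribed an oral NSAID",
       pred = p_all(ckd_stage_in(3), on_drug("NSAID_ORAL"))),
    sc(15, category = "MS3", necessity = "N", topic = "S3",
       event = "Renal toxicity",
       text = "CKD stage 4 or 5: prescribed an oral NSAID",
       pred = p_all(ckd_stage_in(c(4, 5)), on_drug("NSAID_ORAL"))),
    sc(16, category = "MS4", necessity = "N", topic = "S3",
       event = "Renal toxicity",
       text = "Age >= 65 on ACE inhibitor/ARB (no diuretic): co-prescribed an oral NSAID",
       pred = p_all(age_ge(65), on_drug("ACEI_ARB"),
                    p_not(on_drug("DIURETIC")), on_drug("NSAID_ORAL"))),
    sc(17, category = "MS4", necessity = "N", topic = "S3",
       event = "Renal toxicity",
       text = "Age >= 75 on a diuretic (no ACE inhibitor/ARB): co-prescribed an oral NSAID",
       pred = p_all(age_ge(75), on_drug("DIURETIC"),
                    p_not(on_drug("ACEI_ARB")), on_drug("NSAID_ORAL"))),
    sc(18, category = "MS4", necessity = "N", topic = "S3",
       event = "Renal toxicity",
       text = "On ACE inhibitor/ARB and a diuretic: co-prescribed an oral NSAID",
       pred = p_all(on_drug("ACEI_ARB"), on_drug("DIURETIC"),
                    on_drug("NSAID_ORAL"))),
    sc(19, category = "MS4", necessity = "I", topic = "S3",
       event = "Renal toxicity",
       text = "Age <= 65 on ACE inhibitor/ARB (no diuretic): co-prescribed an oral NSAID",
       pred = p_all(age_le(65), on_drug("ACEI_ARB"),
                    p_not(on_drug("DIURETIC")), on_drug("NSAID_ORAL"))),
    sc(20, category = "MS4", necessity = "I", topic = "S3",
       event = "Renal toxicity",
       text = "Age 65-74 on a diuretic (no ACE inhibitor/ARB): co-prescribed an oral NSAID",
       pred = p_all(age_between(65, 74), on_drug("DIURETIC"),
                    p_not(on_drug("ACEI_ARB")), on_drug("NSAID_ORAL"))),
    sc(21, category = "MS2", necessity = "N", topic = "S4",
       event = "Cardiovascular events",
       text = "On low-dose aspirin: prescribed an oral COX-2 selective NSAID",
       pred = p_all(lda, on_drug("COX2"))),
    sc(22, category = "MS3", necessity = "N", topic = "S5",
       event = "Vascular events",
       text = "Age > 40 with 10-year CVD risk > 20%: prescribed a COX-2 selective NSAID",
       pred = p_all(age_gt(40), risk_score_gt("cvd10y_percent", 20),
                    on_drug("COX2"))),
    sc(23, category = "MS3", necessity = "N", topic = "S5",
       event = "Vascular events",
       text = "History of vascular events: prescribed a COX-2 selective NSAID",
       pred = p_all(has_condition("VASCULAR_EVENT"), on_drug("COX2"))),
    sc(24, category = "MS8", necessity = "N", topic = "S6",
       event = "Electrolyte imbalance",
       text = "On a potassium-sparing diuretic: no U&E check before treatment start",
       pred = p_all(on_drug("K_SPARING_DIURETIC"),
                    no_observation_before_start("UE",
                                                "K_SPARING_DIURETIC"))),
    sc(25, category = "MS8", necessity = "N", topic = "S6",
       event = "Electrolyte imbalance",
       text = "On a potassium-sparing diuretic: no U&E check in the last 48 weeks",
       pred = p_all(on_drug("K_SPARING_DIURETIC"),
                    no_observation_within("UE", 48))),
    sc(26, category = "MS8", necessity = "N", topic = "S6",
       event = "Electrolyte imbalance",
       text = "On a loop diuretic: no U&E check before treatment start",
       pred = p_all(on_drug("LOOP_DIURETIC"),
                    no_observation_before_start("UE", "LOOP_DIURETIC"))),
    sc(27, category = "MS8", necessity = "N", topic = "S6",
       event = "Electrolyte imbalance",
       text = "On a loop plus thiazide diuretic or metolazone: no U&E check in the last 24 weeks",
       pred = p_all(on_drug("LOOP_DIURETIC"),
                    p_any(on_drug("THIAZIDE"), on_drug("METOLAZONE")),
                    no_observation_within("UE", 24))),
    sc(28, category = "MS8", necessity = "N", topic = "S6",
       event = "Electrolyte imbalance",
       text = "On a potassium-sparing diuretic and ACE inhibitor/ARB: no U&E check in the last 48 weeks",
       pred = p_all(on_drug("K_SPARING_DIURETIC"), on_drug("ACEI_ARB"),
                    no_observation_within("UE", 48))),
    sc(29, category = "MS8", necessity = "I", topic = "S6",
       event = "Electrolyte imbalance",
       text = "On a potassium-wasting diuretic: no U&E check in the last 48 weeks",
       pred = p_all(on_drug("K_WASTING_DIURETIC"),
                    no_observation_within("UE", 48))),
    sc(30, category = "MS8", necessity = "I", topic = "S6",
       event = "Electrolyte imbalance",
       text = "On a potassium-sparing diuretic and ACE inhibitor/ARB: no U&E check in the last 24 weeks",
       pred = p_all(on_drug("K_SPARING_DIURETIC"), on_drug("ACEI_ARB"),
                    no_observation_within("UE", 24))),
    sc(31, category = "MS3", necessity = "N", topic = "S7",
       event = "Renal toxicity / treatment failure",
       text = "CKD stage 4 or 5: prescribed a thiazide diuretic",
       pred = p_all(ckd_stage_in(c(4, 5)), on_drug("THIAZIDE"))),
    sc(32, category = "MS1", necessity = "N", topic = "S8",
       event = "Gout",
       text = "History of gout on a thiazide diuretic: no allopurinol",
       pred = p_all(has_condition("GOUT"), on_drug("THIAZIDE"),
                    p_not(on_drug("ALLOPURINOL")))),
    sc(33, category = "MS3", necessity = "N", topic = "S9",
       event = "Hyperkalaemia",
       text = "CKD stage 4 or 5: prescribed an aldosterone antagonist",
       pred = p_all(ckd_stage_in(c(4, 5)),
                    on_drug("ALDOSTERONE_ANTAGONIST"))),
    sc(34, category = "MS6", necessity = "N", topic = "S10",
       event = "Hyperkalaemia",
       text = "On a potassium-sparing diuretic: potassium supplement for >= 4 weeks",
       pred = p_all(on_drug("K_SPARING_DIURETIC"),
                    exposure_weeks_ge("K_SUPPLEMENT", 4))),
    warf_ddi(35, "N", "MACROLIDE", "a macrolide"),
    warf_ddi(36, "N", "SULFONAMIDE", "a sulfonamide"),
    warf_ddi(37, "N", "AZOLE_ANTIFUNGAL", "an azole antifungal"),
    warf_ddi(38, "N", "METRONIDAZOLE", "metronidazole"),
    warf_ddi(39, "N", "CHLORAMPHENICOL", "chloramphenicol"),
    warf_ddi(40, "N", "ISONIAZID", "isoniazid"),
    warf_ddi(41, "N", "RIFAMPICIN", "rifampicin"),
    warf_ddi(42, "N", "GRISEOFULVIN", "griseofulvin"),
    warf_ddi(43, "N", "RIBAVIRIN", "ribavirin"),
    warf_ddi(44, "I", "TETRACYCLINE", "a tetracycline"),
    sc(45, category = "MS2", necessity = "N", topic = "S12",
       event = "Bleeding",
       text = "Atrial fibrillation with CHADS2 = 0: prescribed warfarin",
       pred = p_all(has_condition("AF"), on_drug("WARFARIN"),
                    chads2_eq(0))),
    sc(46, category = "MS1", necessity = "N", topic = "S13",
       event = "Constipation",
       text = "Strong opioid above 10 mg/day oral-morphine equivalent for > 4 weeks: no laxative",
       pred = p_all(on_drug("OPIOID_STRONG"),
                    equivalent_dose_gt("OPIOID_STRONG", 10,
                                       "opioid_morphine"),
                    exposure_weeks_gt("OPIOID_STRONG", 4),
                    p_not(on_drug("LAXATIVE")))),
    sc(47, category = "MS1", necessity = "I", topic = "S13",
       event = "Constipation",
       text = "Age >= 65 on a strong opioid above 10 mg/day oral-morphine equivalent: no laxative",
       pred = p_all(age_ge(65), on_drug("OPIOID_STRONG"),
                    equivalent_dose_gt("OPIOID_STRONG", 10,
                                       "opioid_morphine"),
                    p_not(on_drug("LAXATIVE")))),
    sc(48, category = "MS4", necessity = "N", topic = "S14",
       event = "Bradycardia",
       text = "On a beta blocker: co-prescribed verapamil or diltiazem",
       pred = p_all(on_drug("BETA_BLOCKER"),
                    on_drug("VERAPAMIL_DILTIAZEM"))),
    sc(49, category = "MS3", necessity = "N", topic = "S15",
       event = "Asthma exacerbation",
       text = "Active asthma (beta-agonist inhaler in last year), no COPD: any oral beta blocker",
       pred = p_all(active_asthma, lacks_condition("COPD"),
                    on_drug("BETA_BLOCKER"))),
    sc(50, category = "MS3", necessity = "N", topic = "S15",
       event = "Asthma exacerbation",
       text = "Active asthma, no COPD: a non-cardioselective oral beta blocker",
       pred = p_all(active_asthma, lacks_condition("COPD"),
                    on_drug("BB_NONSELECTIVE"))),
    sc(51, category = "MS3", necessity = "I", topic = "S15",
       event = "Asthma exacerbation",
       text = "Active asthma, no COPD: beta-blocker eye drops",
       pred = p_all(active_asthma, lacks_condition("COPD"),
                    on_drug("BB_EYEDROPS"))),
    sc(52, category = "MS8", necessity = "N", topic = "S6",
       event = "Hyperkalaemia",
       text = "Co-prescribed an ACE inhibitor AND an ARB: no U&E check in the last 24 weeks",
       pred = p_all(on_drug("ACEI"), on_drug("ARB"),
                    no_observation_within("UE", 24))),
    sc(53, category = "MS8", necessity = "N", topic = "S6",
       event = "Hyperkalaemia",
       text = "On an ACE inhibitor or ARB: no U&E check before treatment start",
       pred = p_all(on_drug("ACEI_ARB"),
                    no_observation_before_start("UE", "ACEI_ARB"))),
    sc(54, category = "MS3", necessity = "N", topic = "S16",
       event = "Lactic acidosis",
       text = "CKD stage 4 or 5: prescribed metformin",
       pred = p_all(ckd_stage_in(c(4, 5)), on_drug("METFORMIN"))),
    sc(55, category = "MS3", necessity = "N", topic = "S17",
       event = "Hypoglycaemia",
       text = "CKD stage 4 or 5: a sulphonylurea other than gliclazide or tolbutamide",
       pred = p_all(ckd_stage_in(c(4, 5)),
                    on_drug("SULPHONYLUREA_LONG_ACTING"))),
    sc(56, category = "MS5", necessity = "N", topic = "S18",
       event = "Digoxin toxicity",
       text = "Age >= 65: digoxin >= 250 mcg/day",
       pred = p_all(age_ge(65),
                    daily_dose_ge("DIGOXIN", 250, unit = "mcg/day"))),
    sc(57, category = "MS5", necessity = "N", topic = "S18",
       event = "Digoxin toxicity",
       text = "CKD stage 3, 4 or 5 (eGFR < 60): digoxin >= 250 mcg/day",
       pred = p_all(ckd_stage_in(c(3, 4, 5)),
                    daily_dose_ge("DIGOXIN", 250, unit = "mcg/day"))),
    dig_ddi(58, "AMIODARONE", "amiodarone"),
    dig_ddi(59, "PROPAFENONE", "propafenone"),
    dig_ddi(60, "CHLOROQUINE_HCQ", "chloroquine/hydroxychloroquine"),
    dig_ddi(61, "QUININE", "quinine"),
    dig_ddi(62, "CCB_DIGOXIN_INTERACTING",
            "an interacting calcium channel blocker"),
    dig_ddi(63, "CICLOSPORIN", "ciclosporin"),
    sc(64, category = "MS8", necessity = "N", topic = "S8",
       event = "Digoxin toxicity",
       text = "On a potassium-wasting diuretic and digoxin: last U&E check before treatment start",
       pred = p_all(on_drug("K_WASTING_DIURETIC"), on_drug("DIGOXIN"),
                    no_observation_since_start("UE",
                                               c("K_WASTING_DIURETIC",
                                                 "DIGOXIN")))),
    sc(65, category = "MS8", necessity = "N", topic = "S8",
       event = "Digoxin toxicity",
       text = "On a potassium-wasting diuretic and digoxin: last U&E check > 48 weeks ago",
       pred = p_all(on_drug("K_WASTING_DIURETIC"), on_drug("DIGOXIN"),
                    no_observation_within("UE", 48))),
    sc(66, category = "MS1", necessity = "N", topic = "S19",
       event = "Bone fracture",
       text = "Age >= 65 on an oral corticosteroid for >= 12 weeks: no bone protection",
       pred = p_all(age_ge(65),
                    exposure_weeks_ge("CORTICOSTEROID_ORAL", 12),
                    p_not(on_drug("BONE_PROTECT_STEROID")))),
    sc(67, category = "MS1", necessity = "N", topic = "S19",
       event = "Bone fracture",
       text = "Low-trauma fracture on an oral corticosteroid for >= 12 weeks: no bone protection",
       pred = p_all(has_condition("LOW_TRAUMA_FRACTURE"),
                    exposure_weeks_ge("CORTICOSTEROID_ORAL", 12),
                    p_not(on_drug("BONE_PROTECT_STEROID")))),
    sc(68, category = "MS7", necessity = "N", topic = "S20",
       event = "Methotrexate toxicity",
       text = "On methotrexate: no explicit weekly dosing instructions recorded",
       pred = p_all(on_drug("METHOTREXATE"),
                    no_dose_instructions("METHOTREXATE"))),
    sc(69, category = "MS7", necessity = "N", topic = "S20",
       event = "Methotrexate toxicity",
       text = "On methotrexate: more than one tablet strength prescribed",
       pred = p_all(on_drug("METHOTREXATE"),
                    strengths_gt_one("METHOTREXATE"))),
    fbc(70, "N", "AURANOFIN", "auranofin", 8),
    fbc(71, "N", "AUROTHIOMALATE", "aurothiomalate", 8),
    fbc(72, "N", "PENICILLAMINE", "penicillamine", 8),
    fbc(73, "N", "LEFLUNOMIDE", "leflunomide", 12),
    fbc(74, "N", "METHOTREXATE", "methotrexate", 12),
    fbc(75, "N", "AZATHIOPRINE", "azathioprine", 12),
    fbc(76, "I", "CYCLOPHOSPHAMIDE", "cyclophosphamide", 24),
    fbc(77, "I", "SULFASALAZINE", "sulfasalazine", 24),
    sc(78, category = "MS3", necessity = "N", topic = "S22",
       event = "Vascular events",
       text = "Previous vascular disease/events: any hormone replacement therapy",
       pred = p_all(sex_is("female"),
                    has_condition("VASCULAR_DISEASE_ANY"),
                    on_drug("HRT_ANY"))),
    sc(79, category = "MS3", necessity = "N", topic = "S22",
       event = "Vascular events",
       text = "10-year CVD risk >= 20%: combined hormonal contraceptives",
       pred = p_all(sex_is("female"), risk_score_ge("cvd10y_percent", 20),
                    on_drug("CONTRACEPTIVE_COMBINED"))),
    sc(80, category = "MS3", necessity = "I", topic = "S22",
       event = "Vascular events",
       text = "10-year CVD risk >= 20%, age 50-59: combined HRT",
       pred = p_all(sex_is("female"), risk_score_ge("cvd10y_percent", 20),
                    age_between(50, 59), on_drug("HRT_COMBINED"))),
    sc(81, category = "MS3", necessity = "I", topic = "S22",
       event = "Vascular events",
       text = "10-year CVD risk >= 20%, age >= 60: any HRT",
       pred = p_all(sex_is("female"), risk_score_ge("cvd10y_percent", 20),
                    age_ge(60), on_drug("HRT_ANY"))),
    sc(82, category = "MS6", necessity = "N", topic = "S23",
       event = "Gynaecological cancer",
       text = "Age >= 50: combined HRT for >= 5 years",
       pred = p_all(sex_is("female"), age_ge(50),
                    exposure_weeks_ge("HRT_COMBINED", 260))),
    sc(83, category = "MS3", necessity = "N", topic = "S23",
       event = "Gynaecological cancer",
       text = "Age >= 50 without hysterectomy: estrogens without cyclical progestogen",
       pred = p_all(sex_is("female"), age_ge(50), flag_not("hysterectomy"),
                    on_drug("ESTROGEN_ONLY_HRT"),
                    p_not(on_drug("PROGESTOGEN_CYCLICAL")))),
    sc(84, category = "MS6", necessity = "I", topic = "S23",
       event = "Gynaecological cancer",
       text = "Age >= 50: estrogen-only HRT for >= 5 years",
       pred = p_all(sex_is("female"), age_ge(50),
                    exposure_weeks_ge("ESTROGEN_ONLY_HRT", 260))),
    sc(85, category = "MS8", necessity = "N", topic = "S24",
       event = "Thyroid disturbances",
       text = "On amiodarone: no thyroid function test in the last 9 months (39 weeks)",
       pred = p_all(on_drug("AMIODARONE"),
                    no_observation_within("TFT", 39))),
    sc(86, category = "MS2", necessity = "N", topic = "S25",
       event = "Theophylline toxicity",
       text = "Age >= 65 with COPD on theophylline without a long-acting beta2 agonist or antimuscarinic inhaler",
       pred = p_all(age_ge(65), has_condition("COPD"),
                    on_drug("THEOPHYLLINE"),
                    p_not(on_drug("LABA_OR_ANTIMUSCARINIC_INHALER")))),
    simva_ddi(87, "HIV_PROTEASE_INHIBITOR", "an HIV protease inhibitor", 10),
    simva_ddi(88, "CICLOSPORIN", "ciclosporin", 10),
    simva_ddi(89, "VERAPAMIL", "verapamil", 10),
    simva_ddi(90, "FIBRATE_NOT_FENOFIBRATE", "a fibrate (not fenofibrate)",
              10),
    simva_ddi(91, "AMIODARONE", "amiodarone", 20),
    sc(92, category = "MS3", necessity = "N", topic = "S27",
       event = "Anticholinergic/sedative harm",
       text = "Age >= 65 with dementia: prescribed a tricyclic antidepressant",
       pred = p_all(age_ge(65), has_condition("DEMENTIA"), on_drug("TCA"))),
    sc(93, category = "MS3", necessity = "N", topic = "S27",
       event = "Stroke/death in dementia",
       text = "Age >= 65 with dementia but no psychosis: prescribed an antipsychotic",
       pred = p_all(age_ge(65), has_condition("DEMENTIA"),
                    lacks_condition("PSYCHOSIS"),
                    on_drug("ANTIPSYCHOTIC"))),
    sc(94, category = "MS3", necessity = "N", topic = "S27",
       event = "Stroke/death in dementia",
       text = "Age >= 65 with dementia and psychosis: an antipsychotic other than risperidone",
       pred = p_all(age_ge(65), has_condition("DEMENTIA"),
                    has_condition("PSYCHOSIS"),
                    on_drug("ANTIPSYCHOTIC_NOT_RISPERIDONE"))),
    sc(95, category = "MS3", necessity = "N", topic = "S27",
       event = "Falls/sedation",
       text = "Age >= 65: prescribed a long-acting benzodiazepine",
       pred = p_all(age_ge(65), on_drug("BENZO_LONG_ACTING"))),
    sc(96, category = "MS3", necessity = "N", topic = "S27",
       event = "Extrapyramidal harm",
       text = "Age >= 65 with Parkinson's disease: an antipsychotic other than quetiapine or clozapine",
       pred = p_all(age_ge(65), has_condition("PARKINSONS"),
                    on_drug("ANTIPSYCHOTIC_NOT_QUETIAPINE_CLOZAPINE"))),
    sc(97, category = "MS3", necessity = "N", topic = "S27",
       event = "Extrapyramidal harm",
       text = "Age >= 65 with Parkinson's disease: a phenothiazine antiemetic",
       pred = p_all(age_ge(65), has_condition("PARKINSONS"),
                    on_drug("PHENOTHIAZINE_ANTIEMETIC"))),
    sc(98, category = "MS3", necessity = "N", topic = "S27",
       event = "Anticholinergic/sedative harm",
       text = "Age >= 75: prescribed a tricyclic antidepressant",
       pred = p_all(age_ge(75), on_drug("TCA"))),
    sc(99, category = "MS3", necessity = "N", topic = "S27",
       event = "Falls/sedation",
       text = "Age >= 75: prescribed a short-acting benzodiazepine",
       pred = p_all(age_ge(75), on_drug("BENZO_SHORT_ACTING"))),
    sc(100, category = "MS3", necessity = "N", topic = "S27",
       event = "Falls/sedation",
       text = "Age >= 75: prescribed a Z-drug",
       pred = p_all(age_ge(75), on_drug("Z_DRUG"))),
    sc(101, category = "MS3", necessity = "N", topic = "S27",
       event = "Anticholinergic harm",
       text = "Age >= 75: an antihistamine with antimuscarinic properties",
       pred = p_all(age_ge(75), on_drug("ANTIHISTAMINE_ANTIMUSCARINIC"))),
    sc(102, category = "MS3", necessity = "A", topic = "S27",
       event = "Anticholinergic harm",
       text = "Age >= 85: an antispasmodic with antimuscarinic properties",
       pred = p_all(age_ge(85), on_drug("ANTISPASMODIC_ANTIMUSCARINIC"))),
    sc(103, category = "MS6", necessity = "N", topic = "S27",
       event = "Anticholinergic/sedative harm",
       text = "Age >= 65: tricyclic antidepressant for >= 4 weeks",
       pred = p_all(age_ge(65), exposure_weeks_ge("TCA", 4))),
    sc(104, category = "MS6", necessity = "N", topic = "S27",
       event = "Falls/sedation",
       text = "Age >= 65: short-acting benzodiazepine for >= 4 weeks",
       pred = p_all(age_ge(65),
                    exposure_weeks_ge("BENZO_SHORT_ACTING", 4))),
    sc(105, category = "MS6", necessity = "N", topic = "S27",
       event = "Falls/sedation",
       text = "Age >= 65: Z-drug for >= 4 weeks",
       pred = p_all(age_ge(65), exposure_weeks_ge("Z_DRUG", 4))),
    sc(106, category = "MS6", necessity = "N", topic = "S27",
       event = "Anticholinergic harm",
       text = "Age >= 65: antimuscarinic antispasmodic for >= 4 weeks",
       pred = p_all(age_ge(65),
                    exposure_weeks_ge("ANTISPASMODIC_ANTIMUSCARINIC", 4))),
    sc(107, category = "MS6", necessity = "N", topic = "S27",
       event = "Stroke/death in dementia",
       text = "Age >= 65 with dementia and psychosis: risperidone for >= 12 weeks",
       pred = p_all(age_ge(65), has_condition("DEMENTIA"),
                    has_condition("PSYCHOSIS"),
                    exposure_weeks_ge("RISPERIDONE", 12))),
    sc(108, category = "MS6", necessity = "N", topic = "S27",
       event = "Anticholinergic harm",
       text = "Age 66-75: antimuscarinic antihistamine for >= 4 weeks",
       pred = p_all(age_between(66, 75),
                    exposure_weeks_ge("ANTIHISTAMINE_ANTIMUSCARINIC", 4))),
    sc(109, category = "MS6", necessity = "N", topic = "S27",
       event = "Anticholinergic harm",
       text = "Age >= 75: antimuscarinic urological drug for >= 4 weeks",
       pred = p_all(age_ge(75),
                    exposure_weeks_ge("UROLOGICAL_ANTIMUSCARINIC", 4))),
    chf_avoid(110, "ANTIARRHYTHMIC_1_3_NOT_AMIO",
              "a class 1 or 3 antiarrhythmic other than amiodarone"),
    chf_avoid(111, "VERAPAMIL_DILTIAZEM", "verapamil or diltiazem"),
    chf_avoid(112, "MINOXIDIL", "minoxidil"),
    chf_avoid(113, "NSAID_ORAL", "an oral NSAID"),
    chf_avoid(114, "GLITAZONE", "a glitazone"),
    chf_avoid(115, "TCA", "a tricyclic antidepressant"),
    chf_avoid(116, "ITRACONAZOLE", "itraconazole"),
    chf_avoid(117, "ANTIFUNGAL_SYSTEMIC_OTHER",
              "another systemic antifungal (e.g. ketoconazole, fluconazole)"),
    chf_avoid(118, "TADALAFIL", "tadalafil"),
    chf_avoid(119, "DISULFIRAM", "disulfiram"),
    sc(120, category = "MS3", necessity = "N", topic = "S29",
       event = "Extrapyramidal harm",
       text = "Age <= 20: prescribed a phenothiazine antiemetic",
       pred = p_all(age_le(20), on_drug("PHENOTHIAZINE_ANTIEMETIC"))),
    sc(121, category = "MS3", necessity = "N", topic = "S29",
       event = "Reye's syndrome",
       text = "Age <= 16 without Kawasaki disease: prescribed aspirin",
       pred = p_all(age_le(16), lacks_condition("KAWASAKI"),
                    on_drug("ASPIRIN"))),
    sc(122, category = "MS3", necessity = "N", topic = "S29",
       event = "Dental/bone toxicity",
       text = "Age <= 12: prescribed a tetracycline",
       pred = p_all(age_le(12), on_drug("TETRACYCLINE"))),
    sc(123, category = "MS3", necessity = "N", topic = "S29",
       event = "Self-harm risk",
       text = "Age <= 18: an antidepressant other than fluoxetine",
       pred = p_all(age_le(18), on_drug("ANTIDEPRESSANT_NOT_FLUOXETINE"))),
    sc(124, category = "MS3", necessity = "I", topic = "S29",
       event = "Self-harm risk",
       text = "Age <= 18: prescribed fluoxetine",
       pred = p_all(age_le(18), on_drug("FLUOXETINE")))
  )
}
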