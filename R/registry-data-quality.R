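# The 52 prescribing-quality criteria (Q-001..Q-052). Each predicate
# encodes the UNMET care state: a flag means the stated beneficial
# treatment is absent, below the first-line standard or below target
# intensity at the index date. Intensification criteria (topics Q2/Q3)
# fire when the latest BP/HbA1c reading exceeds its target, the current
# regimen is below the stated drug-class count, the reading is old enough
# for the practice to have responded, and no new drug class was started
# since the reading.

quality_criteria <- function() {
  qc <- function(id_num, ...) {
    crit(sprintf("Q-%03d", id_num), domain = "quality", ...)
  }
  # Q2 helper: hypertension treatment-intensification block
  bp_block <- function(id, necessity, age_pred, complicated, sys, dia, k,
                       text) {
    compl_clause <- if (complicated) has_condition("HTN_COMPLICATION") else
      lacks_condition("HTN_COMPLICATION")
    qc(id, category = "MQ3", necessity = necessity, topic = "Q2",
       event = "Hypertension complications", text = text,
       pred = p_all(has_condition("HYPERTENSION"), age_pred, compl_clause,
                    uncontrolled_bp(sys, dia, k)))
  }
  hb_block <- function(id, necessity, text, ...) {
    qc(id, category = "MQ3", necessity = necessity, topic = "Q3",
       event = "Diabetes complications", text = text,
       pred = p_all(has_condition("DIABETES_T2"),
                    uncontrolled_hba1c(...)))
  }
  microalb <- p_any(has_condition("MICROALBUMINURIA"), obs_gt("ACR", 3))
  overweight <- p_any(has_condition("OVERWEIGHT"), obs_ge("BMI", 25))

  bind_rows(
    qc(1, category = "MQ2", necessity = "N", topic = "Q1",
       event = "Hypertension complications",
       text = "Hypertension without CHD: on antihypertensive treatment but none is a first-line agent",
       pred = p_all(has_condition("HYPERTENSION"), lacks_condition("CHD"),
                    on_drug("ANTIHYPERTENSIVE"),
                    p_not(on_drug("FIRSTLINE_ANTIHYPERTENSIVE")))),
    bp_block(2, "N", age_le(74), FALSE, 150, 90, 3,
             "Uncomplicated hypertension, age < 75: BP > 150/90 on < 3 antihypertensive classes, not intensified"),
    bp_block(3, "N", age_le(74), FALSE, 140, 85, 2,
             "Uncomplicated hypertension, age < 75: BP > 140/85 on < 2 antihypertensive classes, not intensified"),
    bp_block(4, "A", age_le(74), FALSE, 140, 85, 3,
             "Uncomplicated hypertension, age < 75: BP > 140/85 on < 3 antihypertensive classes, not intensified"),
    bp_block(5, "N", age_ge(75), FALSE, 150, 90, 2,
             "Uncomplicated hypertension, age >= 75: BP > 150/90 on < 2 antihypertensive classes, not intensified"),
    bp_block(6, "N", age_ge(75), FALSE, 140, 85, 1,
             "Uncomplicated hypertension, age >= 75: BP > 140/85 without antihypertensive treatment"),
    bp_block(7, "A", age_ge(75), FALSE, 150, 90, 3,
             "Uncomplicated hypertension, age >= 75: BP > 150/90 on < 3 antihypertensive classes, not intensified"),
    bp_block(8, "A", age_ge(75), FALSE, 140, 85, 2,
             "Uncomplicated hypertension, age >= 75: BP > 140/85 on < 2 antihypertensive classes, not intensified"),
    bp_block(9, "N", age_le(74), TRUE, 130, 80, 2,
             "Complicated hypertension, age < 75: BP > 130/80 on < 2 antihypertensive classes, not intensified"),
    bp_block(10, "N", age_ge(75), TRUE, 140, 85, 2,
             "Complicated hypertension, age >= 75: BP > 140/85 on < 2 antihypertensive classes, not intensified"),
    bp_block(11, "N", age_ge(75), TRUE, 130, 80, 1,
             "Complicated hypertension, age >= 75: BP > 130/80 without antihypertensive treatment"),
    bp_block(12, "A", age_ge(75), TRUE, 140, 85, 3,
             "Complicated hypertension, age >= 75: BP > 140/85 on < 3 antihypertensive classes, not intensified"),
    bp_block(13, "A", age_ge(75), TRUE, 130, 80, 2,
             "Complicated hypertension, age >= 75: BP > 130/80 on < 2 antihypertensive classes, not intensified"),
    hb_block(14, "N", gt = 7, max_classes = 2,
             text = "Type 2 diabetes: HbA1c > 7% on < 2 oral antidiabetic classes, not intensified"),
    hb_block(15, "N", gt = 9, max_classes = 3,
             text = "Type 2 diabetes: HbA1c > 9% on < 3 oral antidiabetic classes, not intensified"),
    hb_block(16, "A", between = c(6.6, 7), max_classes = 1,
             text = "Type 2 diabetes: HbA1c 6.6-7% without antidiabetic treatment"),
    hb_block(17, "A", between = c(7.6, 9), max_classes = 3,
             text = "Type 2 diabetes: HbA1c 7.6-9% on < 3 oral antidiabetic classes, not intensified"),
    qc(18, category = "MQ2", necessity = "N", topic = "Q4",
       event = "Diabetes complications",
       text = "Overweight type 2 diabetic on oral antidiabetic treatment not including metformin",
       pred = p_all(has_condition("DIABETES_T2"), overweight,
                    on_drug("ANTIDIABETIC_ORAL"),
                    p_not(on_drug("METFORMIN")))),
    qc(19, category = "MQ1", necessity = "N", topic = "Q5",
       event = "Diabetes complications",
       text = "Diabetes with micro-albuminuria: no ACE inhibitor or ARB",
       pred = p_all(has_condition("DIABETES"), microalb,
                    p_not(on_drug("ACEI_ARB")))),
    qc(20, category = "MQ1", necessity = "N", topic = "Q6",
       event = "Vascular events",
       text = "Previous vascular event (MI, stroke or TIA): no statin",
       pred = p_all(has_condition("VASCULAR_EVENT"),
                    p_not(on_drug("STATIN")))),
    qc(21, category = "MQ1", necessity = "N", topic = "Q6",
       event = "Vascular events",
       text = "Peripheral vascular disease: no statin",
       pred = p_all(has_condition("PVD"), p_not(on_drug("STATIN")))),
    qc(22, category = "MQ1", necessity = "N", topic = "Q6",
       event = "Vascular events",
       text = "Age > 40 with diabetes, no established vascular disease: no statin",
       pred = p_all(age_gt(40), has_condition("DIABETES"),
                    lacks_condition("VASCULAR_DISEASE_ANY"),
                    p_not(on_drug("STATIN")))),
    qc(23, category = "MQ1", necessity = "A", topic = "Q6",
       event = "Vascular events",
       text = "10-year CVD risk > 20% without diabetes: no statin",
       pred = p_all(risk_score_gt("cvd10y_percent", 20),
                    lacks_condition("DIABETES"),
                    p_not(on_drug("STATIN")))),
    qc(24, category = "MQ4", necessity = "N", topic = "Q7",
       event = "Vascular events",
       text = "Previous vascular event: statin below simvastatin 40 mg/day equivalent",
       pred = p_all(has_condition("VASCULAR_EVENT"),
                    p_not(equivalent_dose_ge("STATIN", 40,
                                             "statin_simvastatin")))),
    qc(25, category = "MQ4", necessity = "N", topic = "Q7",
       event = "Vascular events",
       text = "Peripheral vascular disease: statin below simvastatin 40 mg/day equivalent",
       pred = p_all(has_condition("PVD"),
                    p_not(equivalent_dose_ge("STATIN", 40,
                                             "statin_simvastatin")))),
    qc(26, category = "MQ4", necessity = "N", topic = "Q7",
       event = "Vascular events",
       text = "Age > 40 with diabetes, no vascular disease: statin below simvastatin 40 mg/day equivalent",
       pred = p_all(age_gt(40), has_condition("DIABETES"),
                    lacks_condition("VASCULAR_DISEASE_ANY"),
                    p_not(equivalent_dose_ge("STATIN", 40,
                                             "statin_simvastatin")))),
    qc(27, category = "MQ4", necessity = "N", topic = "Q7",
       event = "Vascular events",
       text = "10-year CVD risk > 20% without diabetes: statin below simvastatin 40 mg/day equivalent",
       pred = p_all(risk_score_gt("cvd10y_percent", 20),
                    lacks_condition("DIABETES"),
                    p_not(equivalent_dose_ge("STATIN", 40,
                                             "statin_simvastatin")))),
    qc(28, category = "MQ1", necessity = "N", topic = "Q8",
       event = "Vascular events",
       text = "Previous vascular event: no thrombo-embolic prophylaxis",
       pred = p_all(has_condition("VASCULAR_EVENT"),
                    p_not(on_drug("ANTITHROMBOTIC")))),
    qc(29, category = "MQ1", necessity = "N", topic = "Q8",
       event = "Vascular events",
       text = "Peripheral vascular disease: no thrombo-embolic prophylaxis",
       pred = p_all(has_condition("PVD"),
                    p_not(on_drug("ANTITHROMBOTIC")))),
    qc(30, category = "MQ1", necessity = "N", topic = "Q8",
       event = "Vascular events",
       text = "Previous stroke/TIA: not on aspirin plus dipyridamole (unless on warfarin or clopidogrel)",
       pred = p_all(has_condition("STROKE_TIA"),
                    p_not(p_all(on_drug("ASPIRIN"),
                                on_drug("DIPYRIDAMOLE"))),
                    p_not(p_any(on_drug("WARFARIN"),
                                on_drug("CLOPIDOGREL"))))),
    qc(31, category = "MQ1", necessity = "N", topic = "Q8",
       event = "Vascular events",
       text = "ACS 0-3 months ago: not on aspirin plus clopidogrel (unless on warfarin)",
       pred = p_all(condition_onset_within_months("ACS", 0, 3),
                    p_not(p_all(on_drug("ASPIRIN"),
                                on_drug("CLOPIDOGREL"))),
                    p_not(on_drug("WARFARIN")))),
    qc(32, category = "MQ1", necessity = "A", topic = "Q8",
       event = "Vascular events",
       text = "ACS 4-9 months ago: not on aspirin plus clopidogrel (unless on warfarin)",
       pred = p_all(condition_onset_within_months("ACS", 4, 9),
                    p_not(p_all(on_drug("ASPIRIN"),
                                on_drug("CLOPIDOGREL"))),
                    p_not(on_drug("WARFARIN")))),
    qc(33, category = "MQ1", necessity = "N", topic = "Q9",
       event = "Vascular events",
       text = "History of acute coronary syndrome: no beta blocker",
       pred = p_all(has_condition("ACS"), p_not(on_drug("BETA_BLOCKER")))),
    qc(34, category = "MQ1", necessity = "N", topic = "Q9",
       event = "Vascular events",
       text = "Stable angina without a history of ACS: no beta blocker",
       pred = p_all(has_condition("ANGINA"), lacks_condition("ACS"),
                    p_not(on_drug("BETA_BLOCKER")))),
    qc(35, category = "MQ1", necessity = "N", topic = "Q10",
       event = "Vascular events",
       text = "History of acute coronary syndrome: no ACE inhibitor or ARB",
       pred = p_all(has_condition("ACS"), p_not(on_drug("ACEI_ARB")))),
    qc(36, category = "MQ1", necessity = "A", topic = "Q10",
       event = "Vascular events",
       text = "Stable angina without a history of ACS: no ACE inhibitor or ARB",
       pred = p_all(has_condition("ANGINA"), lacks_condition("ACS"),
                    p_not(on_drug("ACEI_ARB")))),
    qc(37, category = "MQ1", necessity = "N", topic = "Q11",
       event = "Heart failure progression",
       text = "Chronic heart failure: no ACE inhibitor or ARB",
       pred = p_all(has_condition("CHF"), p_not(on_drug("ACEI_ARB")))),
    qc(38, category = "MQ1", necessity = "N", topic = "Q12",
       event = "Heart failure progression",
       text = "Chronic heart failure: no beta blocker",
       pred = p_all(has_condition("CHF"), p_not(on_drug("BETA_BLOCKER")))),
    qc(39, category = "MQ2", necessity = "A", topic = "Q12",
       event = "Heart failure progression",
       text = "Chronic heart failure on a beta blocker not licensed for heart failure",
       pred = p_all(has_condition("CHF"), on_drug("BETA_BLOCKER"),
                    p_not(on_drug("BB_LICENSED_CHF")))),
    qc(40, category = "MQ4", necessity = "N", topic = "Q13",
       event = "Heart failure progression",
       text = "Chronic heart failure on ACE inhibitor/ARB below the recommended target dose",
       pred = p_all(has_condition("CHF"), on_drug("ACEI_ARB"),
                    below_target_dose("ACEI_ARB"))),
    qc(41, category = "MQ4", necessity = "N", topic = "Q13",
       event = "Heart failure progression",
       text = "Chronic heart failure on a beta blocker below the recommended target dose",
       pred = p_all(has_condition("CHF"), on_drug("BETA_BLOCKER"),
                    below_target_dose("BETA_BLOCKER"))),
    qc(42, category = "MQ1", necessity = "N", topic = "Q14",
       event = "Stroke / embolism",
       text = "Atrial fibrillation, CHADS2 0-1: no thrombo-embolic prophylaxis",
       pred = p_all(has_condition("AF"), chads2_between(0, 1),
                    p_not(on_drug("ANTITHROMBOTIC")))),
    qc(43, category = "MQ1", necessity = "N", topic = "Q14",
       event = "Stroke / embolism",
       text = "Atrial fibrillation, CHADS2 = 2: no thrombo-embolic prophylaxis",
       pred = p_all(has_condition("AF"), chads2_eq(2),
                    p_not(on_drug("ANTITHROMBOTIC")))),
    qc(44, category = "MQ1", necessity = "N", topic = "Q14",
       event = "Stroke / embolism",
       text = "Atrial fibrillation, CHADS2 >= 3: no thrombo-embolic prophylaxis",
       pred = p_all(has_condition("AF"), chads2_ge(3),
                    p_not(on_drug("ANTITHROMBOTIC")))),
    qc(45, category = "MQ2", necessity = "N", topic = "Q15",
       event = "Stroke / embolism",
       text = "Atrial fibrillation, CHADS2 >= 3, on an antithrombotic but no oral anticoagulant",
       pred = p_all(has_condition("AF"), chads2_ge(3),
                    on_drug("ANTITHROMBOTIC"),
                    p_not(on_drug("ORAL_ANTICOAGULANT")))),
    qc(46, category = "MQ1", necessity = "N", topic = "Q16",
       event = "Asthma exacerbation",
       text = "Asthma (age > 4, no COPD) on a step-3 drug without an inhaled corticosteroid",
       pred = p_all(age_gt(4), has_condition("ASTHMA"),
                    lacks_condition("COPD"),
                    on_drug("STEP3_ASTHMA_DRUG"), p_not(on_drug("ICS")))),
    qc(47, category = "MQ1", necessity = "N", topic = "Q16",
       event = "Asthma exacerbation",
       text = "Asthma (age > 4, no COPD) with oral prednisolone in the last 12 weeks, no inhaled corticosteroid",
       pred = p_all(age_gt(4), has_condition("ASTHMA"),
                    lacks_condition("COPD"),
                    issues_in_window_ge("PREDNISOLONE_ORAL", 1, 12),
                    p_not(on_drug("ICS")))),
    qc(48, category = "MQ1", necessity = "N", topic = "Q16",
       event = "Asthma exacerbation",
       text = "Asthma (age > 4, no COPD) with >= 3 SABA issues in the last 12 weeks, no inhaled corticosteroid",
       pred = p_all(age_gt(4), has_condition("ASTHMA"),
                    lacks_condition("COPD"),
                    issues_in_window_ge("SABA", 3, 12),
                    p_not(on_drug("ICS")))),
    qc(49, category = "MQ1", necessity = "A", topic = "Q16",
       event = "Asthma exacerbation",
       text = "Asthma (age > 4, no COPD) with 2 SABA issues in the last 12 weeks, no inhaled corticosteroid",
       pred = p_all(age_gt(4), has_condition("ASTHMA"),
                    lacks_condition("COPD"),
                    issues_in_window_eq("SABA", 2, 12),
                    p_not(on_drug("ICS")))),
    qc(50, category = "MQ1", necessity = "N", topic = "Q17",
       event = "Fractures",
       text = "Female with osteoporosis and a vertebral fracture: no bone-protecting agent",
       pred = p_all(sex_is("female"), has_condition("OSTEOPOROSIS"),
                    has_condition("VERTEBRAL_FRACTURE"),
                    p_not(on_drug("BONE_PROTECT_OSTEOPOROSIS")))),
    qc(51, category = "MQ1", necessity = "N", topic = "Q18",
       event = "Fractures",
       text = "Housebound female aged >= 80: no calcium and vitamin D",
       pred = p_all(sex_is("female"), age_ge(80), flag_is("housebound"),
                    p_not(on_drug("CALCIUM_VITD")))),
    qc(52, category = "MQ1", necessity = "N", topic = "Q18",
       event = "Fractures",
       text = "Female aged >= 80 in nursing home/residential care: no calcium and vitamin D",
       pred = p_all(sex_is("female"), age_ge(80), flag_is("nursing_home"),
                    p_not(on_drug("CALCIUM_VITD"))))
  )
}
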