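# Regenerates the plain-text fixtures under inst/extdata/. Run from the
# repository root: Rscript data-raw/make_fixtures.R
suppressMessages(devtools::load_all(".", quiet = TRUE))
out <- file.path("inst", "extdata")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

## 1. default hierarchy (57 leaves) ------------------------------------------
write_hierarchy(build_default_hierarchy(), file.path(out, "hierarchy_gen1.json"),
  format = "json"
)

## 2. generation-1 question manifest (209 placeholder questions) -------------
h_ext <- build_default_hierarchy(include_catch_alls = TRUE)
counts <- c(
  "Cognitive/Behavioral/Emotional/Adaptability" = 4,
  "Cognitive/Behavioral/Emotional/Anger Control" = 5,
  "Cognitive/Behavioral/Emotional/Anxiety" = 17,
  "Cognitive/Behavioral/Emotional/Depression" = 5,
  "Cognitive/Behavioral/Emotional/Mood" = 3,
  "Cognitive/Behavioral/Emotional/Obsessive Compulsive" = 4,
  "Cognitive/Behavioral/Emotional/Paranoia" = 1,
  "Cognitive/Behavioral/Emotional/Emotional" = 8,
  "Cognitive/Behavioral/Sensory/Disturbed" = 1,
  "Cognitive/Behavioral/Sensory/Intrigued" = 1,
  "Cognitive/Behavioral/Sensory/Sensory" = 3,
  "Cognitive/Behavioral/Social/Aggression" = 3,
  "Cognitive/Behavioral/Social/Atypicality" = 6,
  "Cognitive/Behavioral/Social/Awareness" = 11,
  "Cognitive/Behavioral/Social/Comforting" = 1,
  "Cognitive/Behavioral/Social/Conduct" = 14,
  "Cognitive/Behavioral/Social/Ego" = 1,
  "Cognitive/Behavioral/Social/Eye Contact" = 1,
  "Cognitive/Behavioral/Social/Group Play" = 2,
  "Cognitive/Behavioral/Social/Imitation" = 1,
  "Cognitive/Behavioral/Social/Joint Attention" = 3,
  "Cognitive/Behavioral/Social/Leadership" = 1,
  "Cognitive/Behavioral/Social/Maturity" = 1,
  "Cognitive/Behavioral/Social/Reciprocal Interactions" = 2,
  "Cognitive/Behavioral/Social/Relationships" = 4,
  "Cognitive/Behavioral/Social/Shared Interests" = 4,
  "Cognitive/Behavioral/Social/Smile" = 1,
  "Cognitive/Behavioral/Social/Staring" = 1,
  "Cognitive/Behavioral/Social/Withdrawal" = 4,
  # published count 8, +2 reconciliation rows (see README)
  "Cognitive/Behavioral/Social/Social" = 10,
  "Cognitive/Language & Communication/Expressive" = 12,
  "Cognitive/Language & Communication/Nonverbal" = 2,
  "Cognitive/Language & Communication/Receptive" = 5,
  "Cognitive/Language & Communication/Speech" = 3,
  "Cognitive/Executive Functioning/Arithmetic" = 1,
  "Cognitive/Executive Functioning/Attention" = 7,
  "Cognitive/Executive Functioning/Confusion" = 1,
  "Cognitive/Executive Functioning/Coping" = 1,
  "Cognitive/Executive Functioning/Fluency" = 3,
  "Cognitive/Executive Functioning/Hyperactivity" = 4,
  "Cognitive/Executive Functioning/Imagination" = 1,
  "Cognitive/Executive Functioning/Impulsivity" = 3,
  "Cognitive/Executive Functioning/Inhibitory Control" = 2,
  "Cognitive/Executive Functioning/Memory" = 3,
  "Cognitive/Executive Functioning/Patience" = 1,
  "Cognitive/Executive Functioning/Perseveration" = 1,
  "Cognitive/Executive Functioning/Planning" = 4,
  "Cognitive/Executive Functioning/Reasoning" = 5,
  "Cognitive/Executive Functioning/Executive Functioning" = 9,
  "Motor/Fine" = 1,
  # published Gross count 4, split evenly over the two sub-leaves
  "Motor/Gross/Locomotion" = 2,
  "Motor/Gross/Coordination" = 2,
  "Somatic/Dermatologic" = 1,
  "Somatic/Fatigue" = 1,
  "Somatic/Gastrointestinal" = 2,
  "Somatic/Illness" = 2,
  "Somatic/Neurologic" = 2,
  "Somatic/Sleep" = 2,
  "Somatic/Vision" = 1,
  "Somatic/Weight" = 1,
  "Somatic/Somatic" = 1
)
stopifnot(sum(counts) == 209, all(names(counts) %in% hierarchy_leaves(h_ext)))
manifest <- purrr::imap_dfr(counts, function(n, leaf) {
  tibble::tibble(
    question_id = sprintf("Cognoa_%s_Q%02d", leaf_token(h_ext, leaf), seq_len(n)),
    leaf = leaf
  )
})
write.csv(manifest, file.path(out, "generation1_manifest.csv"), row.names = FALSE)

## 3. instrument registry (8 instruments, 15 versions) -----------------------
registry <- tibble::tribble(
  ~instrument, ~version, ~reporter, ~n_items, ~scale_kind, ~scale_size,
  "ADI-R", "Standard", "clinician", 93L, "quality", 4L,
  "ADOS-2", "Module 1", "clinician", 29L, "quality", 4L,
  "ADOS-2", "Module 2", "clinician", 28L, "quality", 4L,
  "ADOS-2", "Module 3", "clinician", 28L, "quality", 4L,
  "ADOS-2", "Module 4", "clinician", 38L, "quality", 4L,
  "BASC-3", "Preschool", "parent", 139L, "frequency", 4L,
  "BASC-3", "Child", "parent", 175L, "frequency", 4L,
  "BASC-3", "Adolescent", "parent", 192L, "frequency", 4L,
  "BRIEF2", "Parent", "parent", 63L, "frequency", 3L,
  "CBCL", "Preschool", "parent", 100L, "frequency", 3L,
  "CBCL", "School-age", "parent", 113L, "frequency", 3L,
  "Conners 3", "Parent", "parent", 110L, "frequency", 4L,
  "SRS-2", "Preschool", "parent", 65L, "frequency", 4L,
  "SRS-2", "School-age", "parent", 65L, "frequency", 4L,
  "VADRS", "Parent", "parent", 55L, "frequency", 4L
)
write.csv(registry, file.path(out, "instrument_registry.csv"), row.names = FALSE)

## 4. adaptability worked-example crosswalk ----------------------------------
ex_reg <- dplyr::filter(registry, paste(instrument, version) %in% c(
  "ADI-R Standard", "BASC-3 Preschool", "BASC-3 Child", "BASC-3 Adolescent",
  "BRIEF2 Parent", "CBCL School-age", "Conners 3 Parent", "SRS-2 School-age"
))
adapt_leaf <- "Cognitive/Behavioral/Emotional/Adaptability"
qid <- function(x) paste0("Cognoa_Cognitive_Behavioral_Emotional_Adaptability_", x)
items <- tibble::tribble(
  ~instrument, ~version, ~item, ~subject, ~question,
  # --- RoutineChange: 21 items -------------------------------------------
  "ADI-R", "Standard", "74", "Changes in routine/schedule", "RoutineChange",
  "ADI-R", "Standard", "75", "Changes around the house", "RoutineChange",
  "ADI-R", "Standard", "76", "Reaction to altered schedule [synthetic]", "RoutineChange",
  "ADI-R", "Standard", "77", "Upset by rearranged objects [synthetic]", "RoutineChange",
  "BASC-3", "Preschool", "88", "Changes in surroundings", "RoutineChange",
  "BASC-3", "Child", "47", "Changes to schedule", "RoutineChange",
  "BASC-3", "Adolescent", "156", "Changes at school", "RoutineChange",
  "BASC-3", "Preschool", "112", "Upset by routine changes [synthetic]", "RoutineChange",
  "BASC-3", "Preschool", "29", "Reacts badly to change [synthetic]", "RoutineChange",
  "BASC-3", "Child", "131", "Adjusts to new plans [synthetic]", "RoutineChange",
  "BASC-3", "Adolescent", "33", "Handles schedule changes [synthetic]", "RoutineChange",
  "BRIEF2", "Parent", "11", "Changes to situations", "RoutineChange",
  "BRIEF2", "Parent", "44", "Upset by plan changes [synthetic]", "RoutineChange",
  "BRIEF2", "Parent", "58", "Resists change of routine [synthetic]", "RoutineChange",
  "CBCL", "School-age", "21", "Changes in routine", "RoutineChange",
  "CBCL", "School-age", "84", "Disturbed by change [synthetic]", "RoutineChange",
  "CBCL", "School-age", "97", "Rigid about routines [synthetic]", "RoutineChange",
  "SRS-2", "School-age", "24", "Changes in routine", "RoutineChange",
  "SRS-2", "School-age", "51", "Transitions in routine [synthetic]", "RoutineChange",
  "Conners 3", "Parent", "12", "Upset when routine changes [synthetic]", "RoutineChange",
  "Conners 3", "Parent", "67", "Trouble adjusting to change [synthetic]", "RoutineChange",
  # --- NewPlaces: 4 items --------------------------------------------------
  "BASC-3", "Child", "52", "Uncomfortable in new places [synthetic]", "NewPlaces",
  "SRS-2", "School-age", "16", "Avoids new situations [synthetic]", "NewPlaces",
  "CBCL", "School-age", "46", "Nervous in new situations [synthetic]", "NewPlaces",
  "Conners 3", "Parent", "30", "Avoids unfamiliar settings [synthetic]", "NewPlaces",
  # --- Transitions: 4 items ------------------------------------------------
  "BRIEF2", "Parent", "23", "Trouble with transitions [synthetic]", "Transitions",
  "BRIEF2", "Parent", "71", "Slow to switch activities [synthetic]", "Transitions",
  "BASC-3", "Preschool", "64", "Moves between activities [synthetic]", "Transitions",
  "ADI-R", "Standard", "78", "Difficulty ending activities [synthetic]", "Transitions",
  # --- FlexibleThinking: 3 items -------------------------------------------
  "BRIEF2", "Parent", "80", "Thinks of alternatives [synthetic]", "FlexibleThinking",
  "BASC-3", "Adolescent", "102", "Accepts other solutions [synthetic]", "FlexibleThinking",
  "SRS-2", "School-age", "60", "Insists on the same way [synthetic]", "FlexibleThinking"
)
stopifnot(nrow(items) == 32, sum(items$question == "RoutineChange") == 21)
scale_of <- setNames(ex_reg$scale_size, paste(ex_reg$instrument, ex_reg$version))
items$scale_size <- unname(scale_of[paste(items$instrument, items$version)])
questions <- items |>
  dplyr::group_by(question) |>
  dplyr::summarise(n_codes = answer_code_count(scale_size), .groups = "drop") |>
  dplyr::transmute(
    question_id = qid(question), leaf = adapt_leaf, n_codes,
    phrasing = c(
      FlexibleThinking = "Struggles to consider a different approach when the usual one fails",
      NewPlaces = "Becomes distressed in unfamiliar places or situations",
      RoutineChange = "Becomes unusually upset by small changes to routine, schedule or surroundings",
      Transitions = "Has difficulty moving from one activity to the next"
    )[question]
  )
mappings <- items |>
  dplyr::transmute(instrument, version, item, question_id = qid(question)) |>
  dplyr::mutate(answer_map = purrr::map(
    unname(scale_of[paste(instrument, version)]),
    ~ default_answer_map(.x, 3L)
  ))
cw <- crosswalk(ex_reg, dplyr::select(items, -question), questions, mappings)
stopifnot(nrow(validate_crosswalk(cw)) == 0)
write_crosswalk(cw, file.path(out, "adaptability_crosswalk.yaml"))

## 5. case-study selected features -----------------------------------------
features <- tibble::tribble(
  ~question_id, ~subject,
  "Cognoa_Cognitive_Behavioral_Emotional_AngerControl_CalmingDown", "Child is difficult to calm when upset",
  "Cognoa_Cognitive_Behavioral_Emotional_AnxietyInternalization_Worry", "Child tends to be worrisome",
  "Cognoa_Cognitive_Behavioral_Sensory_Intrigued", "Child has an unusual interest in certain sensory stimuli",
  "Cognoa_Cognitive_Behavioral_Social_Atypicality_OddBehavior", "Others seem to think the child acts strangely",
  "Cognoa_Cognitive_Behavioral_Social_Atypicality_OddInteractions", "Child has awkward interactions with others",
  "Cognoa_Cognitive_Behavioral_Social_Atypicality_OutOfStepWithOthers", "Child does not care about relating to others",
  "Cognoa_Cognitive_Behavioral_Social_Awareness_GetsTakenAdvantageOf", "Child has difficulty recognizing manipulative behavior",
  "Cognoa_Cognitive_Behavioral_Social_Awareness_SenseOfHumor", "Child understands humor",
  "Cognoa_Cognitive_Behavioral_Social_Awareness_Unfair", "Child has difficulty understanding fairness",
  "Cognoa_Cognitive_Behavioral_Social_GroupPlay", "Child participates in group play",
  "Cognoa_Cognitive_Behavioral_Social_SharedInterests_Objects", "Child likes to direct others' attention to objects of interest",
  "Cognoa_Cognitive_Behavioral_Social_SharedInterests_SharingToys", "Child offers to share toys",
  "Cognoa_Cognitive_Behavioral_Social_Staring_BlankStares", "Child tends to stare blankly",
  "Cognoa_Cognitive_Behavioral_Social_Withdrawal_Avoidance", "Child has little interest in others",
  "Cognoa_Cognitive_Behavioral_Social_Imitation", "Child imitates others' behavior",
  "Cognoa_Cognitive_ExecutiveFunctioning_Attention_CarelessMistakes", "Child tends to make careless mistakes",
  "Cognoa_Cognitive_ExecutiveFunctioning_Attention_FollowingDirections", "Child has difficulty following directions",
  "Cognoa_Cognitive_ExecutiveFunctioning_Attention_LosesThings", "Child frequently loses belongings",
  "Cognoa_Cognitive_ExecutiveFunctioning_Imagination_WithToys", "Child uses creativity in play",
  "Cognoa_Cognitive_ExecutiveFunctioning_Impulsivity_OutOfControl", "Child tends to act wild or out of control",
  "Cognoa_Cognitive_ExecutiveFunctioning_Impulsivity_Verbal", "Child tends to blurt out the first thing that comes to mind",
  "Cognoa_Cognitive_ExecutiveFunctioning_Memory_CompleteActivities", "Child tends to be forgetful in everyday tasks",
  "Cognoa_Cognitive_ExecutiveFunctioning_Memory_ShortTerm", "Child has problems with short term memory",
  "Cognoa_Cognitive_ExecutiveFunctioning_Reasoning_LacksFollowThrough", "Child tends to lack follow-through",
  "Cognoa_Cognitive_ExecutiveFunctioning_CleaningUpAfterSelf", "Child has a tendency to leave behind messes",
  "Cognoa_Cognitive_ExecutiveFunctioning_SloppyWork", "Child has sloppy written work",
  "Cognoa_Cognitive_LanguageCommunication_Expressive_SocialChatting", "Child is comfortable with social chatting",
  "Cognoa_Cognitive_LanguageCommunication_Speech_UnusualOrOdd", "Child has unusual tone or rhythm in speech",
  "Cognoa_Cognitive_LanguageCommunication_Receptive_Conversations", "Child can respond to back-and-forth conversations",
  "Cognoa_Motor_Fine_Grip", "Child has the ability to grip objects"
)
stopifnot(nrow(features) == 30)
write.csv(features, file.path(out, "case_study_features.csv"), row.names = FALSE)

cat("fixtures written to", out, "\n")
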