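"question_id","subject"
"Cognoa_Cognitive_Behavioral_Emotional_AngerControl_CalmingDown","Child is difficult to calm when upset"
"Cognoa_Cognitive_Behavioral_Emotional_AnxietyInternalization_Worry","Child tends to be worrisome"
"Cognoa_Cognitive_Behavioral_Sensory_Intrigued","Child has an unusual interest in certain sensory stimuli"
"Cognoa_Cognitive_Behavioral_Social_Atypicality_OddBehavior","Others seem to think the child acts strangely"
"Cognoa_Cognitive_Behavioral_Social_Atypicality_OddInteractions","Child has awkward interactions with others"
"Cognoa_Cognitive_Behavioral_Social_Atypicality_OutOfStepWithOthers","Child does not care about relating to others"
"Cognoa_Cognitive_Behavioral_Social_Awareness_GetsTakenAdvantageOf","Child has difficulty recognizing manipulative behavior"
"Cognoa_Cognitive_Behavioral_Social_Awareness_SenseOfHumor","Child understands humor"
"Cognoa_Cognitive_Behavioral_Social_Awareness_Unfair","Child has difficulty understanding fairness"
"Cognoa_Cognitive_Behavioral_Social_GroupPlay","Child participates in group play"
"Cognoa_Cognitive_Behavioral_Social_SharedInterests_Objects","Child likes to direct others' attention to objects of interest"
"Cognoa_Cognitive_Behavioral_Social_SharedInterests_SharingToys","Child offers to share toys"
"Cognoa_Cognitive_Behavioral_Social_Staring_BlankStares","Child tends to stare blankly"
"Cognoa_Cognitive_Behavioral_Social_Withdrawal_Avoidance","Child has little interest in others"
"Cognoa_Cognitive_Behavioral_Social_Imitation","Child imitates others' behavior"
"Cognoa_Cognitive_ExecutiveFunctioning_Attention_CarelessMistakes","Child tends to make careless mistakes"
"Cognoa_Cognitive_ExecutiveFunctioning_Attention_FollowingDirections","Child has difficulty following directions"
"Cognoa_Cognitive_ExecutiveFunctioning_Attention_LosesThings","Child frequently loses belongings"
"Cognoa_Cognitive_ExecutiveFunctioning_Imagination_WithToys","Child uses creativity in play"
"Cognoa_Cognitive_ExecutiveFunctioning_Impulsivity_OutOfControl","Child tends to act wild or out of control"
"Cognoa_Cognitive_ExecutiveFunctioning_Impulsivity_Verbal","Child tends to blurt out the first thing that comes to mind"
"Cognoa_Cognitive_ExecutiveFunctioning_Memory_CompleteActivities","Child tends to be forgetful in everyday tasks"
"Cognoa_Cognitive_ExecutiveFunctioning_Memory_ShortTerm","Child has problems with short term memory"
"Cognoa_Cognitive_ExecutiveFunctioning_Reasoning_LacksFollowThrough","Child tends to lack follow-through"
"Cognoa_Cognitive_ExecutiveFunctioning_CleaningUpAfterSelf","Child has a tendency to leave behind messes"
"Cognoa_Cognitive_ExecutiveFunctioning_SloppyWork","Child has sloppy written work"
"Cognoa_Cognitive_LanguageCommunication_Expressive_SocialChatting","Child is comfortable with social chatting"
"Cognoa_Cognitive_LanguageCommunication_Speech_UnusualOrOdd","Child has unusual tone or rhythm in speech"
"Cognoa_Cognitive_LanguageCommunication_Receptive_Conversations","Child can respond to back-and-forth conversations"
"Cognoa_Motor_Fine_Grip","Child has the ability to grip objects"
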