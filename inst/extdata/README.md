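# Packaged generation-1 fixtures

All fixtures are plain text and are reconstructed from the published
generation-1 mapping tables; entries marked `[synthetic]` are stand-ins
invented to reach the published counts where the source tables print only
examples.

## hierarchy_gen1.json

The default semantic hierarchy: Cognitive (Behavioral -> Emotional, Sensory,
Social; Language & Communication; Executive Functioning), Motor (Fine;
Gross -> two sub-leaves) and Somatic, 57 leaf categories in total.

Two documented reconciliations:

* The published narrative counts 57 leaves, but the per-leaf fusion table
  has 60 distinct leaf rows: it adds subgroup-level catch-all rows named
  after their own subgroup for Emotional, Sensory, Executive Functioning
  and Somatic (the Social catch-all is already one of Social's 19 leaves).
  This fixture follows the narrative 57-leaf reading;
  `build_default_hierarchy(include_catch_alls = TRUE)` adds the four
  catch-all leaves (61 leaves) so every row of the fusion table has a leaf.
* The two gross-motor sub-leaves are not named in the published material;
  the labels `Locomotion` and `Coordination` are fixture metadata, not
  published semantics.

## generation1_manifest.csv

Placeholder question ids per leaf category, per-leaf counts taken from the
published fusion table (using the catch-all leaves above). The printed
per-leaf question counts sum to 207 while the published grand total is 209;
the fixture reconciles by adding 2 placeholder questions to the Social
catch-all leaf (the broadest residual bucket). The published Gross-motor
count of 4 is split evenly across the two sub-leaves.

## instrument_registry.csv

The 8 covered instruments expanded into 15 instrument versions (ADI-R 1;
ADOS-2 4 modules; BASC-3 3 forms; BRIEF2 1; CBCL 2; Conners 3 1; SRS-2 2;
VADRS 1). Published material gives only per-instrument question-count
ranges; per-version `n_items` values are synthetic but lie inside the
published ranges. `scale_kind`/`scale_size` follow the published answer
scale examples (quality scales for the clinician instruments, frequency
scales elsewhere).

## adaptability_crosswalk.yaml

The worked example for the Adaptability leaf: 32 items from 6 instruments
(ADI-R, BASC-3, BRIEF2, CBCL, Conners 3, SRS-2) fused into 4 questions,
21 of the items mapping to the routine-change question. The published
material prints 8 of the 32 item subjects; the rest are `[synthetic]`
stand-ins with abbreviated subject labels (no instrument item text is
reproduced). All answer maps use the default severe-end collapse onto 3
consolidated codes.

## case_study_features.csv

The 30 question ids (with short subject labels) selected by the machine
learning case study.
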