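Fixture provenance
==================

battery_default.json
  The shipped default battery: ten tests from five instruments with their
  VP/VMC recruitment weights (mean recruitment 76/24).

table2_worked_example.csv
  The worked example profile: ten z-scores whose derived quantities are
  avg z -1.65, eta 140.5, mu 24.5, eta_exp 125.4, mu_exp 39.6.

table3_pre.csv
  Four subjects before treatment. subj3 completed only 7 of 10 tests
  (refused the three Corsi working-memory tests); expected indices for that
  session use the administered-subset mean weights (460/7, 240/7).

table4_post_literal.csv
  The same four subjects after treatment, transcribed as printed in the
  source table, including two known inconsistencies:
  - subj1 corsi_simultaneous 10.72 contradicts that column's own derived
    values (printed avg z -0.21, eta 13.95, mu 7.05);
  - subj4's printed mu (21.08) disagrees with its own z-scores, which give
    21.80, consistent with the printed delta_mu 4.40.
  One printed value, subj3 bhk_velocity "-0-48", is transcribed as -0.48,
  which reproduces that column's derived values exactly.

table4_post_corrected.csv
  Identical to the literal file except subj1 corsi_simultaneous = 1.72,
  the unique value consistent with the printed avg z (-0.21), eta (13.95)
  and mu (7.05) of that column. Use this variant for pre/post comparisons.
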