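id,gene,age_inclusion,age_last_obs,age_hysterectomy,age_bso,age_ec_dx,age_oc_dx,age_death,died_of_followup_cancer
W001,MLH1,25,40,,,,,,
W002,MLH1,30.5,45.25,,,,,,
W003,MLH1,38,51.5,,,43.5,,,
W004,MLH1,42,47,,,46,,47,true
W005,MLH1,25,40,27,,,,,
W006,MSH2,35,50,45,45,,,,
W007,MSH2,29.75,44.75,,,,,,
W008,MSH2,40,55,,,,48.2,,
W009,MSH2,50,62,,,,55,58.6,true
W010,MSH2,33,34.5,,,,,,
W011,MSH6,27,52,,,,,,
W012,MSH6,45,60,52,52,52,,,
W013,MSH6,31.2,46,,,31.2,,,
W014,MSH6,58,70.5,,,,,,
W015,PMS2,36,66,,,,,,
W016,PMS2,52,67,,,57.9,,,
W017,PMS2,44,58,50,50,,,,
W018,MLH1,64,74.9,,,,,,
W019,MSH2,70,79,,,73.99,,,
W020,MSH6,25,26,,,26,,,
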