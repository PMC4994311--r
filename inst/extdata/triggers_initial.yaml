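# Initial thresholds used during the first silent-surveillance phase,
# before tuning raised the early-refill threshold (0.30 -> 0.50) and
# lowered the ED/urgent-care visit minimum (3 -> 2).
remaining_fraction_threshold: 0.30
min_ed_uc_visits: 3
ed_uc_window_days: 30
min_prescriptions: 3
rx_window_days: 30
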