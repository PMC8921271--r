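# Canonical dose-response study conditions, shared with scripts/acceptance.R.
series_spec <- function(seed = 1) damage_series_conditions(seed)$spec
series_doses <- damage_series_conditions()$doses
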