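# The three study conditions at production settings are expensive enough to
# share across test files; computed once per test run.
.scn_memo <- new.env(parent = emptyenv())

get_scenarios <- function() {
  if (is.null(.scn_memo$scn)) {
    .scn_memo$scn <- suppressWarnings(
      lapply(stats::setNames(nm = c("normal", "hf", "hf_lvad")),
             run_scenario))
  }
  .scn_memo$scn
}

get_summaries <- function() {
  if (is.null(.scn_memo$sm))
    .scn_memo$sm <- suppressWarnings(
      lapply(get_scenarios(), summarize_scenario))
  .scn_memo$sm
}

get_last_beats <- function() {
  if (is.null(.scn_memo$beats))
    .scn_memo$beats <- lapply(get_scenarios(), function(s)
      segment_last_beat(s$traces, s$bcl_ms))
  .scn_memo$beats
}
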