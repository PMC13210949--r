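# the desk-scale study is expensive (two training runs); run it once per
# test session and share the result across acceptance blocks
get_desk_study <- function() {
  if (is.null(.fixture_env$study)) {
    .fixture_env$study <- desk_study(seed = 42L)
  }
  .fixture_env$study
}
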