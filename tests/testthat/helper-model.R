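# Shared heavyweight fixtures, built once per test run: a 200-hairpin
# planted-signal set split 140 train / 60 held-out, and the model trained on
# the training split. Scales chosen to keep the whole suite to a few
# minutes while leaving the held-out evaluation statistically meaningful.

.shared_env <- new.env(parent = emptyenv())

shared_fixture <- function() {
  if (is.null(.shared_env$data)) {
    spec <- fixture_spec(seed = 20240801L, n_hairpins = 200L)
    hp <- make_hairpins(spec)
    train_mirs <- hp$mirs[1:140]
    test_mirs <- hp$mirs[141:200]
    model <- train_matpred(train_mirs, config = list(seed = 101L))
    .shared_env$data <- list(spec = spec, hairpins = hp,
                             train_mirs = train_mirs, test_mirs = test_mirs,
                             model = model)
  }
  .shared_env$data
}
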