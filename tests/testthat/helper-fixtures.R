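# Shared fixtures, built once per test run and cached.
.fx <- new.env(parent = emptyenv())

fixture_small <- function() {
  if (is.null(.fx$small)) .fx$small <- make_golden_fixture("small")
  .fx$small
}

fixture_medium <- function() {
  if (is.null(.fx$medium)) .fx$medium <- make_golden_fixture("medium")
  .fx$medium
}

fixture_medium_null <- function() {
  if (is.null(.fx$medium_null))
    .fx$medium_null <- simulate_study(null_simulation_config(seed = 202L))
  .fx$medium_null
}

features_small <- function() {
  if (is.null(.fx$feat_small)) {
    s <- fixture_small()
    .fx$feat_small <- assemble_features(s$net, s$catalog, s$dep)
  }
  .fx$feat_small
}

features_medium <- function() {
  if (is.null(.fx$feat_medium)) {
    s <- fixture_medium()
    .fx$feat_medium <- assemble_features(s$net, s$catalog, s$dep)
  }
  .fx$feat_medium
}

cv_medium <- function() {
  if (is.null(.fx$cv_medium))
    .fx$cv_medium <- ocsvm_cross_validate(features_medium(),
                                          fixture_medium()$catalog$members$DTG,
                                          k = 5L, repeats = 10L, seed = 202L)
  .fx$cv_medium
}

# tiny deterministic catalog + network used across files
toy_net <- function() {
  network_from_edges(data.frame(
    from = c("A", "B", "C", "C", "D"),
    to   = c("B", "C", "D", "E", "E")))
}

toy_catalog <- function() {
  gene_catalog(DTG = c("A", "B"), DAG = c("B", "D"), PUG = "E")
}

write_gene_list <- function(lines) {
  f <- withr::local_tempfile(fileext = ".txt",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
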