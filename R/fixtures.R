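fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "rosettabank")
  if (p == "") abort(sprintf("fixture file '%s' not found in installed package", file))
  p
}

#' Packaged generation-1 fixtures
#'
#' Loads one of the plain-text fixtures shipped with the package:
#'
#' * `"default_hierarchy"`: the 57-leaf generation-1 hierarchy
#'   (see [build_default_hierarchy()]).
#' * `"generation1_manifest"`: the 209-question generation-1 manifest, a
#'   tibble of placeholder question ids per leaf category (per-leaf counts
#'   follow the published fusion table; see `inst/extdata/README.md` for
#'   the reconciliation of its totals).
#' * `"instrument_registry"`: the 15 instrument versions of the 8 covered
#'   instruments with reporter, item counts and default answer scales.
#' * `"adaptability_excerpt"`: the worked-example crosswalk for the
#'   Adaptability leaf (32 items from 6 instruments fused into 4
#'   questions), with the default hierarchy attached.
#' * `"case_study_features"`: the 30 question ids (and short subject
#'   labels) selected by the autism/ADHD case study.
#'
#' @param name Fixture name, as above.
#' @return The fixture object (a hierarchy, crosswalk, or tibble).
#' @examples
#' nrow(load_fixture("case_study_features")) # 30
#' @export
load_fixture <- function(name) {
  switch(name,
    default_hierarchy = read_hierarchy(fixture_path("hierarchy_gen1.json")),
    generation1_manifest = tibble::as_tibble(utils::read.csv(
      fixture_path("generation1_manifest.csv"),
      check.names = FALSE
    )),
    instrument_registry = tibble::as_tibble(utils::read.csv(
      fixture_path("instrument_registry.csv"),
      check.names = FALSE
    )),
    adaptability_excerpt = {
      cw <- read_crosswalk(fixture_path("adaptability_crosswalk.yaml"))
      cw$hierarchy <- build_default_hierarchy()
      cw
    },
    case_study_features = tibble::as_tibble(utils::read.csv(
      fixture_path("case_study_features.csv"),
      check.names = FALSE
    )),
    abort(sprintf(
      "unknown fixture '%s'; available: default_hierarchy, generation1_manifest, instrument_registry, adaptability_excerpt, case_study_features",
      name
    ))
  )
}
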