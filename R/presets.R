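#' Packaged genetic-architecture presets for exemplar diseases
#'
#' The package ships architecture parameter sets for a panel of inherited
#' conditions (cardiomyopathies, arrhythmia syndromes, connective-tissue
#' disorders, and the recessive primary ciliary dyskinesia), each with the
#' maximum credible AF and maximum tolerated reference allele count it
#' implies, for use as worked examples and regression anchors.
#'
#' @param name disease name (case-insensitive); see [disease_presets()] for
#'   the available set.
#' @return a list with elements `name`, `label`, `architecture` (a
#'   [disease_architecture()]), `expected_max_credible_af`,
#'   `expected_max_tolerated_ac`, `reference_an`, and, where recorded,
#'   `commonest_variant` (label, carriers, total, unit).
#' @examples
#' hcm <- disease_preset("HCM")
#' max_credible_af(hcm$architecture)
#' @export
disease_preset <- function(name) {
  db <- load_presets()
  key <- match(tolower(name), tolower(names(db$diseases)))
  if (is.na(key))
    stop("unknown disease preset '", name, "'; available: ",
         paste(names(db$diseases), collapse = ", "), call. = FALSE)
  d <- db$diseases[[key]]
  arch <- disease_architecture(
    prevalence = d$prevalence,
    inheritance = d$inheritance,
    max_allelic_contribution = d$max_allelic_contribution,
    penetrance = d$penetrance,
    max_genetic_contribution = d$max_genetic_contribution,
    disease = d$label)
  list(name = names(db$diseases)[[key]],
       label = d$label,
       architecture = arch,
       expected_max_credible_af = d$expected_max_credible_af,
       expected_max_tolerated_ac = d$expected_max_tolerated_ac,
       reference_an = db$reference_an,
       commonest_variant = d$commonest_variant)
}

#' @rdname disease_preset
#' @return for `disease_presets()`, a data.frame summarising all packaged
#'   presets.
#' @export
disease_presets <- function() {
  db <- load_presets()
  rows <- lapply(names(db$diseases), function(nm) {
    d <- db$diseases[[nm]]
    data.frame(name = nm, label = d$label, inheritance = d$inheritance,
               prevalence = d$prevalence,
               max_allelic_contribution = d$max_allelic_contribution,
               max_genetic_contribution =
                 if (is.null(d$max_genetic_contribution)) NA_real_
                 else d$max_genetic_contribution,
               penetrance = d$penetrance,
               max_credible_af = d$expected_max_credible_af,
               max_tolerated_ac = d$expected_max_tolerated_ac,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

preset_cache <- new.env(parent = emptyenv())

load_presets <- function() {
  if (is.null(preset_cache$db)) {
    path <- system.file("extdata", "disease_presets.json",
                        package = "credaf", mustWork = TRUE)
    preset_cache$db <- jsonlite::read_json(path, simplifyVector = FALSE)
  }
  preset_cache$db
}
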