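## Derived glycan traits: exact linear combinations of measured peaks.
##
## The plasma panel (GP1-GP39) defines 16 derived traits (LB, HB, G0-G4,
## S0-S4, Bisecting, OligoMan, CoreF, AntF); the IgG panel (IGP1-IGP24)
## defines 9 (G0-G2, S0-S2, Bisecting, OligoMan, CoreF). GP2 co-elutes an
## oligomannose with an agalactosylated bisected structure, so it enters
## each of its classes with weight 1/2. Definitions are shipped as CSV
## (panel, trait, peak, weight) so the transcription is reviewable.

trait_descriptions <- c(
  LB        = "mono- and biantennary structures",
  HB        = "tri- and tetraantennary structures",
  G0        = "agalactosylated structures",
  G1        = "monogalactosylated structures",
  G2        = "digalactosylated structures",
  G3        = "trigalactosylated structures",
  G4        = "tetragalactosylated structures",
  S0        = "asialylated structures",
  S1        = "monosialylated structures",
  S2        = "disialylated structures",
  S3        = "trisialylated structures",
  S4        = "tetrasialylated structures",
  Bisecting = "structures containing bisecting GlcNAc",
  OligoMan  = "oligomannosidic structures",
  CoreF     = "structures containing core fucose",
  AntF      = "structures containing antennary fucose"
)

#' Load the bundled derived-trait definitions for a glycan panel
#'
#' Returns the derived glycan traits of the total plasma (16 traits over
#' GP1-GP39) or IgG (9 traits over IGP1-IGP24) N-glycome panel. Each trait
#' is a linear combination of directly measured chromatographic peaks with
#' weights 1 or 1/2 (1/2 for the co-eluting GP2 split).
#'
#' @param panel `"plasma"` or `"igg"`
#' @param file optional path to a definitions CSV with columns
#'   `panel, trait, peak, weight`; defaults to the bundled file
#' @return a list of `TraitDefinition` objects: each a list with `name`,
#'   `coefficients` (named numeric of peak weights) and `description`
#' @export
#' @examples
#' defs <- load_trait_definitions("igg")
#' length(defs)  # 9
load_trait_definitions <- function(panel = c("plasma", "igg"), file = NULL) {
  panel <- match.arg(panel)
  file <- file %||% extdata_path(sprintf("trait_definitions_%s.csv", panel))
  tab <- read.csv(file, stringsAsFactors = FALSE)
  assert_that(all(c("trait", "peak", "weight") %in% names(tab)),
              "definitions file must have columns trait, peak, weight")
  tab <- tab[tab$panel == panel | is.null(tab$panel), , drop = FALSE]
  pk <- peak_names(panel)
  bad <- setdiff(tab$peak, pk)
  assert_that(length(bad) == 0, "unknown peaks in definitions: %s",
              paste(bad, collapse = ", "))
  assert_that(all(tab$weight %in% c(1, 0.5)), "trait weights must be 1 or 1/2")
  defs <- lapply(split(tab, factor(tab$trait, levels = unique(tab$trait))),
    function(d) {
      co <- setNames(d$weight, d$peak)
      structure(list(name = d$trait[1], coefficients = co,
                     description = unname(trait_descriptions[d$trait[1]])),
                class = "TraitDefinition")
    })
  defs[unique(tab$trait)]
}

#' @export
print.TraitDefinition <- function(x, ...) {
  cat(sprintf("<TraitDefinition> %s: %s\n  %s\n", x$name,
              x$description %||% "", paste(
                ifelse(x$coefficients == 1, names(x$coefficients),
                       paste0(names(x$coefficients), "/2")),
                collapse = " + ")))
  invisible(x)
}

#' Compute derived glycan traits from a peak matrix
#'
#' Traits are sums of peak relative areas (weights 1 or 1/2) and are only
#' meaningful on a linear (percent or percent-adjusted) scale; pass the
#' back-transformed matrix after batch correction.
#'
#' @param peaks numeric matrix or data frame, subjects x peaks, columns
#'   named by peak; a [glyco_matrix] on a percent scale is also accepted
#' @param defs list of trait definitions from [load_trait_definitions()]
#' @return numeric matrix, subjects x traits, with attribute `panel` when
#'   it can be inferred from the peak names
#' @export
compute_derived_traits <- function(peaks, defs) {
  if (inherits(peaks, "glyco_matrix")) {
    assert_that(attr(peaks, "scale") %in% c("percent", "percent-adjusted"),
                "traits require a percent-scale matrix, got scale '%s'",
                attr(peaks, "scale"))
    peaks <- unclass_matrix(peaks)
  }
  m <- as.matrix(as.data.frame(peaks))
  all_peaks <- unique(unlist(lapply(defs, function(d) names(d$coefficients))))
  missing <- setdiff(all_peaks, colnames(m))
  assert_that(length(missing) == 0, "peak columns missing: %s",
              paste(missing, collapse = ", "))
  W <- matrix(0, ncol(m), length(defs),
              dimnames = list(colnames(m), vapply(defs, `[[`, "", "name")))
  for (d in defs) W[names(d$coefficients), d$name] <- d$coefficients
  out <- m %*% W
  panel <- if (all(grepl("^IGP", all_peaks))) "igg" else
           if (all(grepl("^GP", all_peaks))) "plasma" else NA_character_
  attr(out, "panel") <- panel
  out
}

#' Validate the structural partition identities of the trait definitions
#'
#' For the plasma panel the galactosylation classes (G0-G4), the
#' sialylation classes (S0-S4) and the branching classes (LB, HB) must
#' each, together with OligoMan, cover every one of the 39 peaks with
#' total weight exactly 1 (GP2 split 1/2 + 1/2; GP7 and GP19 appear only
#' in OligoMan). For the IgG panel G0+G1+G2 and S0+S1+S2 each cover every
#' peak except IGP20 with weight 1, with IGP5 (oligomannose) counted in
#' G0/S0 as printed. IGP20 belongs to no galactosylation or sialylation
#' class in the published trait system; it is validated as weight 0.
#'
#' @param defs list of trait definitions
#' @param panel `"plasma"` or `"igg"`
#' @return a data frame with one row per (partition, peak): columns
#'   `partition`, `peak`, `weight`, `expected`, `ok`; attribute `pass`
#'   is TRUE when every row is ok
#' @export
validate_partitions <- function(defs, panel = c("plasma", "igg")) {
  panel <- match.arg(panel)
  pk <- peak_names(panel)
  partitions <- if (panel == "plasma") {
    list(galactosylation = c("G0", "G1", "G2", "G3", "G4", "OligoMan"),
         sialylation     = c("S0", "S1", "S2", "S3", "S4", "OligoMan"),
         branching       = c("LB", "HB", "OligoMan"))
  } else {
    list(galactosylation = c("G0", "G1", "G2"),
         sialylation     = c("S0", "S1", "S2"))
  }
  by_name <- setNames(defs, vapply(defs, `[[`, "", "name"))
  rows <- do.call(rbind, lapply(names(partitions), function(pn) {
    members <- partitions[[pn]]
    missing <- setdiff(members, names(by_name))
    w <- setNames(numeric(length(pk)), pk)
    for (tr in intersect(members, names(by_name))) {
      co <- by_name[[tr]]$coefficients
      w[names(co)] <- w[names(co)] + co
    }
    expected <- rep(1, length(pk))
    if (panel == "igg") expected[pk == "IGP20"] <- 0
    data.frame(partition = pn, peak = pk, weight = unname(w),
               expected = expected,
               ok = abs(unname(w) - expected) < 1e-12 & length(missing) == 0)
  }))
  attr(rows, "pass") <- all(rows$ok)
  rows
}
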