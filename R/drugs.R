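#' Bundled drug molecules (synthetic geometries)
#'
#' Loads one of the three chemotherapy drugs studied with the carbon
#' carriers: fluorouracil (C4H3FN2O2), proflavine (C13H11N3) and methylene
#' blue (C16H18ClN3S, chloride salt). The shipped structures are synthetic:
#' MMFF94-optimized 3D geometries generated from the molecular graphs, not
#' experimentally refined conformers (file names carry a `_synthetic`
#' suffix). Since all three chromophores are rigid planar ring systems, the
#' force-field geometry is an accurate stand-in for database conformers.
#'
#' Preparation applied on load: chloride counterions are stripped (the ion
#' contributes nothing to adsorption) and the molecule is centered at its
#' center of mass, the default placement convention of the optimizer.
#'
#' @param name `"fluorouracil"`, `"proflavine"` or `"methylene_blue"` (codes
#'   `"FU"`, `"PF"`, `"MB"` also accepted).
#' @param center center at the COM (default TRUE).
#' @param strip_ions strip counterions (default TRUE).
#' @return A [molecule()].
#' @examples
#' drug_molecule("FU")
#' @export
drug_molecule <- function(name, center = TRUE, strip_ions = TRUE) {
  key <- .drug_key(name)
  file <- system.file("extdata", paste0(key, "_synthetic.sdf"),
                      package = "nanosorb", mustWork = TRUE)
  m <- read_sdf(file, name = key)
  if (strip_ions) m <- suppressWarnings(strip_counterions(m))
  if (center) m <- center_molecule(m)
  m
}

.drug_key <- function(name) {
  map <- c(fluorouracil = "fluorouracil", fu = "fluorouracil",
           proflavine = "proflavine", pf = "proflavine",
           methylene_blue = "methylene_blue", mb = "methylene_blue")
  key <- map[tolower(name)]
  if (is.na(key)) {
    stop("unknown drug '", name,
         "'; use fluorouracil/FU, proflavine/PF or methylene_blue/MB")
  }
  unname(key)
}

.drug_code <- function(name) {
  c(fluorouracil = "FU", proflavine = "PF", methylene_blue = "MB")[.drug_key(name)]
}

#' Default front-atom selector for a bundled drug
#'
#' The front vector points from the center of mass toward a designated
#' heteroatom: the unique fluorine for fluorouracil, the central (acridine)
#' nitrogen for proflavine -- resolved as the nitrogen nearest the center of
#' mass, which separates it from the two terminal amines -- and the ring
#' sulfur for methylene blue. Selectors are configurable; these defaults
#' merely fix a reproducible in-plane reference direction.
#'
#' @param name drug name or code (see [drug_molecule()]).
#' @return A selector usable with [select_front_atom()].
#' @export
drug_front_selector <- function(name) {
  switch(.drug_key(name),
         fluorouracil = list(element = "F"),
         proflavine = list(element = "N", rule = "nearest_com"),
         methylene_blue = list(element = "S"))
}
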