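#' Turnover-rate and chemistry tables
#'
#' `default_turnover()` loads the packaged annual turnover rates (yr^-1)
#' used to convert standing biomass into litter: tree components per species
#' (spruce / pine / deciduous) and ground-vegetation classes (moss, lichen,
#' herbs and grasses, dwarf shrubs) above and below ground.  Moss and lichen
#' have no below-ground turnover entry: they contribute no below-ground
#' litter.  `default_awen()` loads the default chemical-quality table
#' partitioning each litter component's carbon into the A/W/E/N compound
#' groups; it is editable configuration, shipped as delimited text.
#'
#' @param file Optional path to an alternative delimited table with the same
#'   header.
#' @return A `data.frame`: `species`, `component`, `rate` for turnover;
#'   `species`, `component`, `A`, `W`, `E`, `N` for chemistry.
#' @export
default_turnover <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "turnover_rates.tsv", package = "awenh",
                        mustWork = TRUE)
  tt <- utils::read.delim(file, comment.char = "#",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("species", "component", "rate") %in% names(tt)))
  if (any(tt$rate <= 0 | tt$rate > 1))
    stop("turnover rates must lie in (0, 1]")
  tt
}

#' @rdname default_turnover
#' @export
default_awen <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "awen_chemistry.tsv", package = "awenh",
                        mustWork = TRUE)
  tt <- utils::read.delim(file, comment.char = "#",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("species", "component", LABILE) %in% names(tt)))
  fr <- as.matrix(tt[, LABILE])
  if (any(fr < 0) || any(abs(rowSums(fr) - 1) > 1e-9))
    stop("AWEN fractions must be >= 0 and sum to 1 per row")
  tt
}

#' Ratio rules for unmeasured biomass components
#'
#' Fine-root biomass (roots < 2 mm) is estimated as 0.3 x foliage biomass;
#' below-ground ground-vegetation biomass as twice the above-ground biomass.
#' Both are simple published ratio rules used when the inventory provides no
#' direct measurement.
#'
#' @param foliage_biomass,above_biomass Biomass, kg C m^-2 (non-negative).
#' @return Derived biomass, kg C m^-2.
#' @export
derive_fine_roots <- function(foliage_biomass) {
  if (any(foliage_biomass < 0)) stop("negative foliage biomass")
  0.3 * foliage_biomass
}

#' @rdname derive_fine_roots
#' @export
derive_ground_veg_below <- function(above_biomass) {
  if (any(above_biomass < 0)) stop("negative ground-vegetation biomass")
  2 * above_biomass
}

TREE_COMPONENTS <- c(foliage = 0, branches = 2, coarse_roots = 2,
                     fine_roots = 0, stem = 10, stump = 10)
GV_CLASSES <- c("moss", "lichen", "herbs", "shrubs")

#' Construct a litter cohort
#'
#' One annual litter mass with its chemical partition and woody size class.
#'
#' @param mass kg C m^-2 yr^-1, non-negative.
#' @param awen Length-4 non-negative vector of A/W/E/N fractions summing to 1.
#' @param size_class Diameter class, cm: 0 (non-woody), 2 (fine woody) or
#'   10 (coarse woody) by default; other values are allowed if the caller
#'   configures matching size classes throughout.
#' @return A list of class `litter_cohort`.
#' @export
litter_cohort <- function(mass, awen, size_class) {
  awen <- as.numeric(awen)
  if (length(awen) != 4L || any(awen < 0) || abs(sum(awen) - 1) > 1e-9)
    stop("awen must be 4 non-negative fractions summing to 1")
  if (!is.finite(mass) || mass < 0) stop("cohort mass must be >= 0")
  if (!is.finite(size_class) || size_class < 0) stop("invalid size class")
  structure(list(mass = mass, awen = setNames(awen, LABILE),
                 size_class = size_class), class = "litter_cohort")
}

lookup_awen <- function(awen_table, species, component) {
  row <- awen_table[awen_table$species == species &
                      awen_table$component == component, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("no unique AWEN chemistry row for species '", species,
         "', component '", component, "'")
  as.numeric(row[1, LABILE])
}

lookup_rate <- function(turnover, species, component) {
  row <- turnover[turnover$species == species &
                    turnover$component == component, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("no unique turnover rate for species '", species,
         "', component '", component, "'")
  row$rate[1]
}

#' Attach chemical quality to a litter mass
#'
#' Looks up the A/W/E/N partition for a species x component combination and
#' returns the finished cohort.  Fails with a named error when the table has
#' no row for the combination.
#'
#' @param mass Litter mass, kg C m^-2 yr^-1.
#' @param species Species or `"ground_veg"`.
#' @param component Component name matching the chemistry table.
#' @param size_class Diameter class, cm.
#' @param awen_table Chemistry table from [default_awen()].
#' @return A `litter_cohort`.
#' @export
assign_awen <- function(mass, species, component, size_class,
                        awen_table = default_awen()) {
  litter_cohort(mass, lookup_awen(awen_table, species, component), size_class)
}

#' Litter from living vegetation
#'
#' Applies annual turnover rates to the standing biomass of a plot: each
#' component sheds `biomass x rate` per year.  Foliage, fine roots and all
#' ground vegetation enter the 0 cm (non-woody) class; branches and coarse
#' roots the 2 cm class.  Living trees shed stems and stumps only through
#' mortality or harvest, so those components contribute nothing here.
#' Below-ground ground-vegetation biomass is taken as twice the above-ground
#' biomass ([derive_ground_veg_below()]); moss and lichen contribute no
#' below-ground litter.
#'
#' @param biomass Named list or vector of biomass components, kg C m^-2:
#'   tree components `foliage`, `branches`, `coarse_roots`, `fine_roots`
#'   (and optionally `stem`, `stump`, ignored here) plus ground-vegetation
#'   above-ground biomass `gv_moss`, `gv_lichen`, `gv_herbs`, `gv_shrubs`.
#'   Missing components are treated as zero.
#' @param species `"spruce"`, `"pine"` or `"deciduous"`.
#' @param turnover Turnover table from [default_turnover()].
#' @param awen_table Chemistry table from [default_awen()].
#' @return A list of `litter_cohort` objects.
#' @export
litter_from_living <- function(biomass, species,
                               turnover = default_turnover(),
                               awen_table = default_awen()) {
  if (!species %in% c("spruce", "pine", "deciduous"))
    stop("unknown species: ", species)
  bm <- function(nm) if (!is.null(biomass[[nm]])) biomass[[nm]] else 0
  cohorts <- list()
  for (comp in c("foliage", "branches", "coarse_roots", "fine_roots")) {
    b <- bm(comp)
    if (b < 0) stop("negative biomass for ", comp)
    rate <- lookup_rate(turnover, species, comp)
    cohorts[[length(cohorts) + 1L]] <-
      assign_awen(b * rate, species, comp, TREE_COMPONENTS[[comp]],
                  awen_table)
  }
  for (cls in GV_CLASSES) {
    above <- bm(paste0("gv_", cls))
    if (above < 0) stop("negative ground-vegetation biomass for ", cls)
    rate_a <- lookup_rate(turnover, "ground_veg", paste0(cls, "_above"))
    cohorts[[length(cohorts) + 1L]] <-
      assign_awen(above * rate_a, "ground_veg", cls, 0, awen_table)
    below_key <- paste0(cls, "_below")
    if (any(turnover$species == "ground_veg" &
              turnover$component == below_key)) {
      below <- derive_ground_veg_below(above)
      rate_b <- lookup_rate(turnover, "ground_veg", below_key)
      cohorts[[length(cohorts) + 1L]] <-
        assign_awen(below * rate_b, "ground_veg", cls, 0, awen_table)
    }
  }
  cohorts
}

#' Litter from natural mortality and harvest
#'
#' A fraction of the stand dies (`mortality_fraction`, per year) and a
#' fraction is harvested (`harvest_fraction`, of the standing stock): dying
#' trees transfer every biomass component into litter in its size class
#' (stems and stumps at 10 cm, branches and coarse roots at 2 cm, foliage
#' and fine roots at 0 cm).  For a commercial harvest the stems are
#' extracted from the system (they become products, out of scope) and only
#' the residues — stumps, branches, foliage and roots — become litter; set
#' `extract_stems = FALSE` for non-commercial extraction rules that leave
#' stems on site.
#'
#' @param biomass Named tree biomass components, kg C m^-2 (as in
#'   [litter_from_living()]).
#' @param species Species name.
#' @param mortality_fraction Fraction of standing biomass dying, in `[0, 1]`.
#' @param harvest_fraction Fraction of standing biomass harvested, in
#'   `[0, 1]`.
#' @param awen_table Chemistry table.
#' @param extract_stems Remove harvested stems from the site (default TRUE).
#' @return A list of `litter_cohort` objects (empty when both fractions are
#'   zero).
#' @export
litter_from_mortality_and_harvest <- function(biomass, species,
                                              mortality_fraction = 0,
                                              harvest_fraction = 0,
                                              awen_table = default_awen(),
                                              extract_stems = TRUE) {
  for (f in c(mortality_fraction, harvest_fraction)) {
    if (!is.finite(f) || f < 0 || f > 1)
      stop("mortality/harvest fractions must lie in [0, 1]")
  }
  bm <- function(nm) if (!is.null(biomass[[nm]])) biomass[[nm]] else 0
  cohorts <- list()
  add <- function(frac, skip_stem) {
    for (comp in names(TREE_COMPONENTS)) {
      if (skip_stem && comp == "stem") next
      mass <- frac * bm(comp)
      if (mass > 0)
        cohorts[[length(cohorts) + 1L]] <<-
          assign_awen(mass, species, comp, TREE_COMPONENTS[[comp]],
                      awen_table)
    }
  }
  if (mortality_fraction > 0) add(mortality_fraction, skip_stem = FALSE)
  if (harvest_fraction > 0) add(harvest_fraction, skip_stem = extract_stems)
  cohorts
}

#' Collapse litter cohorts into pool-input matrices
#'
#' Sums a list of cohorts into the annual input matrix used by the model
#' core: one row per size class, columns A, W, E, N, H (fresh litter carries
#' no humus, so the H column is zero).
#'
#' @param cohorts List of `litter_cohort` objects.
#' @param size_classes Numeric size classes defining the rows (default
#'   `c(0, 2, 10)`).
#' @return A `length(size_classes) x 5` matrix, kg C m^-2 yr^-1.
#' @export
cohorts_to_input <- function(cohorts, size_classes = c(0, 2, 10)) {
  out <- matrix(0, length(size_classes), 5,
                dimnames = list(paste0("d", size_classes), POOLS))
  for (co in cohorts) {
    i <- match(co$size_class, size_classes)
    if (is.na(i)) stop("cohort size class ", co$size_class,
                       " not among configured classes")
    out[i, LABILE] <- out[i, LABILE] + co$mass * co$awen
  }
  out
}

#' Total carbon in a cohort list
#' @param cohorts List of `litter_cohort` objects.
#' @return Total mass, kg C m^-2 yr^-1.
#' @export
litter_total <- function(cohorts) {
  sum(vapply(cohorts, function(co) co$mass, numeric(1)))
}
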