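#' Construct a ParameterTable
#'
#' @param name Short identifier, used as feature-name prefix.
#' @param values Numeric matrix or data.frame with one row per k-mer
#'   (row names) and one column per property. All 4^k k-mers must be
#'   present; rows are reordered lexicographically.
#' @param resolution `"per-step"` (base-pair-step properties) or
#'   `"per-base"` (base-pair-centered properties such as MGW).
#' @return A [ParameterTable-class].
#' @export
parameterTable <- function(name, values, resolution = "per-step") {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("k-mer row names required")
  rownames(values) <- toupper(rownames(values))
  kl <- unique(nchar(rownames(values)))
  if (length(kl) != 1L) stop("all k-mers must have the same length")
  k <- as.integer(kl)
  want <- allKmers(k)
  missing <- setdiff(want, rownames(values))
  if (length(missing) > 0L)
    stop("incomplete table: ", length(missing), " k-mer(s) missing (e.g. ",
         missing[1L], ")")
  if (anyDuplicated(rownames(values))) stop("duplicate k-mers in table")
  values <- values[want, , drop = FALSE]
  storage.mode(values) <- "double"
  new("ParameterTable", name = name, k = k,
      properties = colnames(values), values = values,
      resolution = resolution)
}

#' Load a k-mer parameter table from TSV
#'
#' Expected format: a header row, the k-mer in the first column, one
#' numeric column per property.
#'
#' @param path Path to the TSV file.
#' @param name Table identifier (default: file name without extension).
#' @param resolution See [parameterTable()].
#' @return A [ParameterTable-class].
#' @export
loadParameterTable <- function(path, name = NULL, resolution = "per-step") {
  .assertSingleString(path, "path")
  if (!file.exists(path)) stop("parameter table not found: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("table needs a k-mer column plus >= 1 property")
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cell in parameter table")
  rownames(m) <- df[[1L]]
  parameterTable(name, m, resolution = resolution)
}

#' Write a ParameterTable to TSV
#'
#' @param table A [ParameterTable-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeParameterTable <- function(table, path) {
  stopifnot(is(table, "ParameterTable"))
  df <- data.frame(kmer = rownames(table@values), table@values,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

setMethod("show", "ParameterTable", function(object) {
  cat(sprintf("ParameterTable '%s': %d-mers, %d propert%s (%s)\n",
              object@name, object@k, length(object@properties),
              if (length(object@properties) == 1L) "y" else "ies",
              object@resolution))
})

#' Unified nearest-neighbor thermodynamic table
#'
#' Dinucleotide Gibbs free energy (`dG`, 37 degrees C), enthalpy (`dH`)
#' and entropy (`dS`) from the unified nearest-neighbor parameter set
#' (SantaLucia 1998, PNAS 95:1460). Units: kcal/mol for dG and dH,
#' cal/(mol K) for dS. The ten unique stacks are expanded to all 16
#' dinucleotides by reverse-complement symmetry.
#'
#' @return A [ParameterTable-class] with k = 2 and 3 properties.
#' @export
nearestNeighborThermoTable <- function() {
  nn <- rbind(
    AA = c(-7.9, -22.2, -1.00),
    AT = c(-7.2, -20.4, -0.88),
    TA = c(-7.2, -21.3, -0.58),
    CA = c(-8.5, -22.7, -1.45),
    GT = c(-8.4, -22.4, -1.44),
    CT = c(-7.8, -21.0, -1.28),
    GA = c(-8.2, -22.2, -1.30),
    CG = c(-10.6, -27.2, -2.17),
    GC = c(-9.8, -24.4, -2.24),
    GG = c(-8.0, -19.9, -1.84))
  colnames(nn) <- c("dH", "dS", "dG")
  full <- matrix(NA_real_, nrow = 16L, ncol = 3L,
                 dimnames = list(allKmers(2L), c("dG", "dH", "dS")))
  rc <- function(x) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  for (d in rownames(full)) {
    src <- if (d %in% rownames(nn)) d else rc(d)
    full[d, ] <- nn[src, c("dG", "dH", "dS")]
  }
  parameterTable("thermo", full, resolution = "per-step")
}

## deterministic synthetic values: one N(mean, sd) draw per k-mer per
## property under a fixed internal seed, so every call returns the same
## table
.syntheticTable <- function(name, k, props, means, sds, resolution,
                            seed = 604613) {
  kmers <- allKmers(k)
  m <- .withSeed(seed, {
    vapply(seq_along(props),
           function(j) stats::rnorm(length(kmers), means[j], sds[j]),
           numeric(length(kmers)))
  })
  dimnames(m) <- list(kmers, props)
  parameterTable(name, m, resolution = resolution)
}

#' Synthetic stand-in parameter tables
#'
#' The published pentamer DNA-shape tables and the two base-pair-step
#' parameter sets ("Chen", "Liu") are consumed by this package as
#' pluggable lookup tables; the real published values are not bundled.
#' These constructors generate clearly synthetic stand-ins with
#' realistic means and spreads, deterministic across calls, so the
#' lookup-smooth-summarize chain and the feature-count bookkeeping can
#' run end to end. Swap in measured tables via [loadParameterTable()]
#' for real analyses.
#'
#' `syntheticShapeTable` emits the 13 pentamer shape properties (MGW,
#' HelT, rise, roll, shift, slide, tilt, buckle, opening, ProT, shear,
#' stagger, stretch); `syntheticEPTable` the pentamer electrostatic
#' potential; `syntheticRigidityTable` a dinucleotide rigidity scale;
#' `syntheticChenTable` 12 dinucleotide physicochemical properties;
#' `syntheticLiuTable` the 6 equilibrium base-pair-step parameters plus
#' their 6 force constants.
#'
#' @return A [ParameterTable-class].
#' @name syntheticTables
NULL

#' @rdname syntheticTables
#' @export
syntheticShapeTable <- function() {
  props <- c("MGW", "HelT", "rise", "roll", "shift", "slide", "tilt",
             "buckle", "opening", "ProT", "shear", "stagger", "stretch")
  means <- c(5.1, 34.3, 3.32, 2.0, 0.0, -0.2, 0.0,
             0.5, 1.0, -8.0, 0.0, 0.0, 0.0)
  sds <- c(0.5, 1.5, 0.10, 3.0, 0.3, 0.4, 1.5,
           4.0, 2.0, 3.0, 0.2, 0.2, 0.1)
  .syntheticTable("shape", 5L, props, means, sds, "per-base", seed = 604613)
}

#' @rdname syntheticTables
#' @export
syntheticEPTable <- function() {
  .syntheticTable("ep", 5L, "EP", -5.0, 1.0, "per-base", seed = 604617)
}

#' @rdname syntheticTables
#' @export
syntheticRigidityTable <- function() {
  .syntheticTable("rigidity", 2L, "rigidity", 0.06, 0.02, "per-step",
                  seed = 604619)
}

#' @rdname syntheticTables
#' @export
syntheticChenTable <- function() {
  props <- c("Duplex.free.energy", "Duplex.disrupt.energy",
             "Bending.stiffness", "Protein.deformation",
             "Stabilising.energy", "Propeller.twist",
             "Protein.DNA.twist", "Persistence.length",
             "Melting.temperature", "Z.DNA.energy", "Stacking.energy",
             "Breathing.dynamics")
  .syntheticTable("chen", 2L, props, rep(0, 12L), rep(1, 12L),
                  "per-step", seed = 604621)
}

#' @rdname syntheticTables
#' @export
syntheticLiuTable <- function() {
  props <- c(paste0("eq.", c("tilt", "roll", "twist", "shift", "slide",
                             "rise")),
             paste0("F.", c("tilt", "roll", "twist", "shift", "slide",
                            "rise")))
  means <- c(0, 2.5, 34, 0, -0.3, 3.3, rep(0.04, 6L))
  sds <- c(1.5, 3, 2, 0.3, 0.4, 0.1, rep(0.012, 6L))
  .syntheticTable("liu", 2L, props, means, sds, "per-step", seed = 604623)
}

#' Default structural parameter-table set
#'
#' The full table inventory used for feature extraction: pentamer shape
#' (13 properties) and electrostatic potential, dinucleotide rigidity,
#' nearest-neighbor thermodynamics (dG/dH/dS), and the two 12-property
#' base-pair-step sets. With mean + variance per property this yields
#' the 84 structural features of the full feature space; all tables
#' except the thermodynamic one are synthetic stand-ins (see
#' [syntheticTables]).
#'
#' @return Named list of [ParameterTable-class] objects.
#' @export
defaultParameterTables <- function() {
  list(shape = syntheticShapeTable(),
       ep = syntheticEPTable(),
       rigidity = syntheticRigidityTable(),
       thermo = nearestNeighborThermoTable(),
       chen = syntheticChenTable(),
       liu = syntheticLiuTable())
}
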