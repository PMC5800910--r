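#' Construct a correction panel for one biomarker
#'
#' A correction panel is the set of SNPs used to compute one biomarker's
#' combined genetic effect.  Each row records the level-increasing
#' ("effect") allele, its population frequency `p`, the multiplicative
#' per-allele effect `a` (ratio of geometric-mean levels per copy), and the
#' normalized genotype-effect triple `(e0, e1, e2)` for 0/1/2 copies.  The
#' triple is always recomputed from `(a, p)` via
#' [normalize_genotype_effects()] so that its Hardy-Weinberg weighted mean
#' is exactly one; any `e0/e1/e2` columns in `x` are overwritten.
#'
#' @param x data.frame with columns `rsid`, `effect_allele`,
#'   `effect_allele_freq`, `allelic_effect`; optional `chrom`,
#'   `position_bp` and bookkeeping columns are carried through.
#' @param biomarker label of the biomarker the panel corrects
#'   (`"AFP"`, `"CA19-9"`, `"CEA"`, or any custom label).
#' @return A `correction_panel`: the validated data.frame with columns
#'   `e0`, `e1`, `e2` filled in and attribute `biomarker`.
#' @seealso [load_snp_panel()] for the packaged default panels.
#' @export
correction_panel <- function(x, biomarker) {
  stopifnot(is.data.frame(x), is.character(biomarker), length(biomarker) == 1L)
  req <- c("rsid", "effect_allele", "effect_allele_freq", "allelic_effect")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols)) {
    stop("panel is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (anyDuplicated(x$rsid)) {
    stop("duplicate rsid within the ", biomarker, " panel: ",
         paste(unique(x$rsid[duplicated(x$rsid)]), collapse = ", "))
  }
  p <- x$effect_allele_freq
  a <- x$allelic_effect
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("effect_allele_freq must lie strictly inside (0, 1)")
  }
  if (any(!is.finite(a)) || any(a <= 0)) {
    stop("allelic_effect must be positive")
  }
  triples <- t(mapply(normalize_genotype_effects, a, p))
  x$e0 <- triples[, 1L]
  x$e1 <- triples[, 2L]
  x$e2 <- triples[, 3L]
  structure(x, biomarker = biomarker,
            class = c("correction_panel", "data.frame"))
}

#' Load SNP effect panels
#'
#' Reads a tab-separated panel file (one row per SNP, a `biomarker` column
#' grouping rows into panels) and returns one [correction_panel()] per
#' biomarker.  With `path = NULL` the packaged default panel is used: the
#' 11 SNPs reported to shift serum AFP (2 SNPs), CA19-9 (4) and CEA (5) in
#' an elderly Chinese population, with their published allele frequencies
#' and relative allelic effects.
#'
#' Genotype-effect triples are recomputed from `(allelic_effect,
#' effect_allele_freq)`, so a custom file needs only those columns plus
#' `rsid` and `effect_allele`; any published triple columns
#' (`xx_printed`/`ox_printed`/`oo_printed`) are carried along for
#' cross-checking only.
#'
#' Two notes on the packaged file.  First, effects are keyed by the count
#' of the *level-increasing* allele; for rows where the published genotype
#' ordering runs the other way (`printed_allele_is_effect == FALSE`) the
#' published allele label is retained in `printed_allele` and the
#' `effect_allele` base is a synthetic placeholder, since the source table
#' does not print the second allele (exception: rs1047781, a known A/T
#' polymorphism).  Second, rs3670775 (CEA) and rs3760775 (CA19-9) share a
#' genomic coordinate and are kept as printed; a message flags the
#' collision.
#'
#' @param path path to a panel TSV, or `NULL` for the packaged default.
#' @return Named list of `correction_panel` objects, one per biomarker.
#' @examples
#' panels <- load_snp_panel()
#' vapply(panels, nrow, integer(1))
#' @export
load_snp_panel <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "snp_effect_panel.tsv",
                        package = "gencorrect", mustWork = TRUE)
  }
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"biomarker" %in% names(raw)) {
    stop("panel file must have a 'biomarker' column")
  }
  panels <- lapply(split(raw, factor(raw$biomarker, unique(raw$biomarker))),
                   function(df) {
                     correction_panel(df[setdiff(names(df), "biomarker")],
                                      biomarker = df$biomarker[1L])
                   })
  flag_position_collisions(panels)
  panels
}

# Message (not warn) when distinct rsids across panels share a coordinate:
# legitimate for shared SNPs, but also how a typo in a source table shows up.
flag_position_collisions <- function(panels) {
  all_rows <- do.call(rbind, lapply(panels, function(p) {
    if (all(c("chrom", "position_bp") %in% names(p))) {
      data.frame(rsid = p$rsid, chrom = p$chrom, pos = p$position_bp,
                 stringsAsFactors = FALSE)
    }
  }))
  if (is.null(all_rows)) return(invisible(NULL))
  all_rows <- unique(all_rows)
  key <- paste(all_rows$chrom, all_rows$pos)
  for (k in unique(key[duplicated(key)])) {
    ids <- unique(all_rows$rsid[key == k])
    if (length(ids) > 1L) {
      message("note: distinct rsids share coordinate ", k, ": ",
              paste(ids, collapse = ", "))
    }
  }
  invisible(NULL)
}

#' @exportS3Method base::print
print.correction_panel <- function(x, ...) {
  label <- attr(x, "biomarker")
  cat("Correction panel", if (!is.null(label)) paste("for", label),
      "-", nrow(x), "SNP(s)\n")
  print.data.frame(x, ...)
  invisible(x)
}

# Resolve the panel for one biomarker from a list (by list name, by the
# panel's own biomarker attribute, or positionally as a last resort).
panel_for_marker <- function(panels, marker) {
  if (inherits(panels, "correction_panel")) return(panels)
  label <- if (marker %in% BIOMARKERS) {
    names(BIOMARKERS)[match(marker, BIOMARKERS)]
  } else marker
  if (!is.null(names(panels)) && label %in% names(panels)) {
    return(panels[[label]])
  }
  hit <- which(vapply(panels, function(p) {
    identical(attr(p, "biomarker"), label)
  }, logical(1)))
  if (length(hit) == 1L) return(panels[[hit]])
  pos <- match(label, names(BIOMARKERS))
  if (!is.na(pos) && pos <= length(panels)) return(panels[[pos]])
  stop("no panel found for biomarker ", label)
}

# Unique SNPs across a list of panels, with consistency checks; used by the
# simulator and by VCF orientation.  Returns data.frame rsid/effect_allele/
# effect_allele_freq.
panel_snp_index <- function(panels) {
  if (inherits(panels, "correction_panel")) panels <- list(panels)
  rows <- do.call(rbind, lapply(panels, function(p) {
    data.frame(rsid = p$rsid, effect_allele = p$effect_allele,
               effect_allele_freq = p$effect_allele_freq,
               stringsAsFactors = FALSE)
  }))
  rows <- unique(rows)
  dup <- unique(rows$rsid[duplicated(rows$rsid)])
  if (length(dup)) {
    stop("inconsistent effect allele or frequency across panels for: ",
         paste(dup, collapse = ", "))
  }
  rows
}
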