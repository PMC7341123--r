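#' Classify fertility grades as sterile or fertile
#'
#' On the five-point anther-exsertion/pollen-shed scale, plants of grade I
#' or II are recorded as sterile and grades III to V as fertile.
#'
#' @param grade character vector of grades `"I"`..`"V"`.
#' @return character vector `"sterile"` / `"fertile"`.
#' @export
#' @examples
#' classify_fertility(c("I", "II", "III", "V"))
classify_fertility <- function(grade) {
  if (!all(grade %in% GRADES))
    stop("unknown fertility grade: ",
         paste(unique(grade[!grade %in% GRADES]), collapse = ", "))
  ifelse(grade %in% c("I", "II"), "sterile", "fertile")
}

#' Observed fertile:sterile ratio
#'
#' @param fertile,sterile counts.
#' @param decimals digits for the reported ratio (half-up rounding, report
#'   convention).
#' @return object of class `observed_ratio` with fields `ratio` (numeric,
#'   rounded), `label` (e.g. `"36.76:1"`), and the raw value; when
#'   `sterile == 0` the ratio is `NA` and the label is `"all fertile"`.
#' @export
#' @examples
#' observed_ratio(1213, 33) # 36.76:1
observed_ratio <- function(fertile, sterile, decimals = 2) {
  stopifnot(fertile >= 0, sterile >= 0)
  if (sterile == 0) {
    out <- list(ratio = NA_real_, raw = NA_real_, label = "all fertile",
                fertile = fertile, sterile = sterile)
  } else {
    raw <- fertile / sterile
    r <- round_half_up(raw, decimals)
    out <- list(ratio = r, raw = raw,
                label = sprintf(paste0("%.", decimals, "f:1"), r),
                fertile = fertile, sterile = sterile)
  }
  structure(out, class = "observed_ratio")
}

#' @export
#' @method print observed_ratio
print.observed_ratio <- function(x, ...) {
  cat(x$fertile, "fertile :", x$sterile, "sterile =", x$label, "\n")
  invisible(x)
}

#' Pearson chi-square goodness of fit against a theoretical ratio
#'
#' Tests observed class counts against a Mendelian segregation ratio such
#' as 1:2:1 or 1:1. Expected counts are proportional to the ratio weights;
#' the statistic is the uncorrected Pearson chi-square (no Yates
#' continuity correction) with `length(observed) - 1` degrees of freedom.
#' The statistic is invariant to rescaling the ratio weights.
#'
#' @param observed integer counts (length >= 2, positive total).
#' @param ratio positive theoretical weights, same length.
#' @return object of class `gof_chisq` with `observed`, `ratio`,
#'   `expected`, `statistic`, `df`, `p.value`.
#' @export
#' @examples
#' gof_chisq(c(327, 628, 291), c(1, 2, 1))
gof_chisq <- function(observed, ratio) {
  if (length(observed) != length(ratio) || length(observed) < 2L)
    stop("observed and ratio must have equal length >= 2")
  if (any(observed < 0)) stop("counts must be >= 0")
  if (any(ratio <= 0)) stop("every ratio weight must be > 0")
  total <- sum(observed)
  if (total <= 0) stop("total count must be > 0")
  expected <- total * ratio / sum(ratio)
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  structure(list(observed = observed, ratio = ratio, expected = expected,
                 statistic = stat, df = df,
                 p.value = pchisq(stat, df, lower.tail = FALSE)),
            class = "gof_chisq")
}

#' @export
#' @method print gof_chisq
print.gof_chisq <- function(x, digits = 2, ...) {
  cat("Goodness of fit vs ", paste(x$ratio, collapse = ":"),
      ": X-squared = ", format(round_half_up(x$statistic, digits)),
      ", df = ", x$df,
      ", p = ", format(round_half_up(x$p.value, digits)), "\n", sep = "")
  invisible(x)
}

#' Fertility table: plant counts by grade
#'
#' Validates and normalises a table of plant counts cross-classified by
#' fertility grade (columns `grade_I`..`grade_V`) and optionally by marker
#' genotype class, population and environment, and derives the fertile /
#' sterile / total columns from the grade counts.
#'
#' @param x data.frame with columns `grade_I`..`grade_V` and any of
#'   `population`, `environment`, `genotype`.
#' @return the table with `fertile`, `sterile`, `total` columns appended
#'   (class `fertility_table`).
#' @export
fertility_table <- function(x) {
  gc <- paste0("grade_", GRADES)
  miss <- setdiff(gc, names(x))
  if (length(miss)) stop("missing grade columns: ", paste(miss, collapse = ", "))
  if (any(as.matrix(x[gc]) < 0)) stop("grade counts must be >= 0")
  x$sterile <- x$grade_I + x$grade_II
  x$fertile <- x$grade_III + x$grade_IV + x$grade_V
  x$total <- x$sterile + x$fertile
  class(x) <- c("fertility_table", "data.frame")
  x
}

#' Tabulate a simulated population into a fertility table
#'
#' @param pop list of individuals from [simulate_f2()] or
#'   [simulate_backcross()].
#' @param by_genotype stratify by restorer-locus genotype class.
#' @return a [fertility_table()].
#' @export
tabulate_population <- function(pop, by_genotype = TRUE) {
  grade <- vapply(pop, `[[`, character(1), "grade")
  poplab <- vapply(pop, `[[`, character(1), "pop")
  geno <- if (by_genotype) vapply(pop, rf4_label, character(1))
          else rep("all", length(pop))
  tab <- table(genotype = geno, grade = factor(grade, levels = GRADES))
  df <- data.frame(population = poplab[1], genotype = rownames(tab))
  for (g in GRADES) df[[paste0("grade_", g)]] <- as.integer(tab[, g])
  fertility_table(df)
}

#' Per-genotype fertility summary
#'
#' For each genotype class: fertile and sterile counts, the fully fertile
#' (grade V) percentage of the class total, and the sterile percentage.
#' Percentages are rounded half-up to 2 decimals for report parity; raw
#' proportions are kept alongside.
#'
#' @param x a [fertility_table()] with a `genotype` column; rows with the
#'   same genotype (e.g. different environments) are pooled.
#' @return data.frame with one row per genotype class.
#' @export
#' @examples
#' tab <- fertility_table(data.frame(genotype = "rf4rf4",
#'   grade_I = 16, grade_II = 86, grade_III = 58, grade_IV = 34,
#'   grade_V = 758))
#' genotype_fertility_summary(tab)
genotype_fertility_summary <- function(x) {
  if (!"genotype" %in% names(x)) stop("table has no genotype column")
  agg <- aggregate(x[paste0("grade_", GRADES)],
                   by = list(genotype = x$genotype), FUN = sum)
  agg <- fertility_table(agg)
  pct <- function(num, den) ifelse(den > 0, round_half_up(100 * num / den, 2),
                                   NA_real_)
  data.frame(genotype = agg$genotype,
             fertile = agg$fertile, sterile = agg$sterile, total = agg$total,
             fully_fertile = agg$grade_V,
             fully_fertile_pct = pct(agg$grade_V, agg$total),
             sterile_pct = pct(agg$sterile, agg$total),
             stringsAsFactors = FALSE)
}

#' Read a fertility count table from CSV
#'
#' Accepts either a pre-tabulated count CSV (columns `grade_I`..`grade_V`
#' plus identifiers) or a plant-level CSV (`plant_id`, `population`,
#' `environment`, `grade`, and optionally `genotype`), which is tabulated.
#'
#' @param path CSV file.
#' @return a [fertility_table()].
#' @export
read_fertility_counts <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  if ("grade_I" %in% names(x)) return(fertility_table(x))
  if (!all(c("grade") %in% names(x)))
    stop("CSV must contain grade_I..grade_V columns or a plant-level 'grade' column")
  by <- intersect(c("population", "environment", "genotype"), names(x))
  if (!length(by)) x$population <- "all"
  by <- intersect(c("population", "environment", "genotype"), names(x))
  tab <- aggregate(list(n = rep(1L, nrow(x))),
                   by = c(x[by], list(grade = factor(x$grade, levels = GRADES))),
                   FUN = sum, drop = FALSE)
  tab$n[is.na(tab$n)] <- 0L
  wide <- reshape(tab, idvar = by, timevar = "grade", direction = "wide")
  names(wide) <- sub("^n\\.", "grade_", names(wide))
  rownames(wide) <- NULL
  fertility_table(wide)
}

#' Example maize CMS-C fertility-restoration count tables
#'
#' Observed plant counts from a maize C-type cytoplasmic-male-sterility
#' restorer cross (CMS line x restorer inbred), shipped as plain CSV under
#' `inst/extdata` and used in examples and tests:
#' `"grades"` gives per-population/environment counts by fertility grade;
#' `"genotypes"` stratifies the same populations by the genotype at the
#' main restorer locus (assayed with a locus-targeted InDel marker),
#' together with the theoretical Mendelian ratio each marker class is
#' tested against.
#'
#' @param which `"grades"` or `"genotypes"`.
#' @return a [fertility_table()].
#' @export
#' @examples
#' cms_example_counts("grades")
cms_example_counts <- function(which = c("grades", "genotypes")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   paste0("cms_fertility_", which, ".csv"),
                   package = "bsaqtl", mustWork = TRUE)
  fertility_table(read.csv(f, stringsAsFactors = FALSE))
}
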