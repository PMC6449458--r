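#' Analyze the immanent accents of a score
#'
#' The package's main entry point: slices the score into sonorities, extracts
#' the melodic line, and computes the six accent salience columns — metrical
#' `M`, melodic contour `C`, vertical harmonic `Hv`, horizontal harmonic
#' `Hh`, and the two combined harmonic models `H1` (maximum) and `H2`
#' (style-parameterized) — each on the 0-5 salience scale with its
#' category-specific cutoff and saturation.
#'
#' @param sc a [score] object (from [read_score] or a fixture generator).
#' @param style style class overriding the score's own
#'   (`"baroque_classical"`, `"romantic"`, `"late_romantic"`).
#' @param familiarity a [familiarity_table]; defaults to the bundled
#'   synthetic table (with a message, since real corpus statistics are
#'   preferable).
#' @param melody_strategy see [extract_melody].
#' @param metrical a [metrical_params] object.
#' @param melodic a [melodic_params] object.
#' @param harmonic_style a [style_params] object; defaults to the style's
#'   published parameter row.
#' @param weights a [root_support_weights] vector.
#' @param prepared_counts,negative passed to [harmonic_accents].
#' @return object of class `accent_analysis`: list with `table` (an
#'   [accent_table]), `stream`, `melody`, `score` and the parameter set.
#' @examples
#' fit <- accent_analysis(prelude7_skeleton())
#' summary(fit)
#' @export
accent_analysis <- function(sc, style = NULL, familiarity = NULL,
                            melody_strategy = "skyline",
                            metrical = metrical_params(),
                            melodic = melodic_params(),
                            harmonic_style = NULL,
                            weights = root_support_weights(),
                            prepared_counts = TRUE, negative = "clamp") {
  stopifnot(inherits(sc, "score"))
  style <- style %||% sc$style
  if (is.null(familiarity)) {
    message("no familiarity table supplied; using the bundled synthetic table")
    familiarity <- default_familiarity()
  }
  hstyle <- harmonic_style %||% style_params(style)
  stream <- chordify(sc)
  melody <- extract_melody(sc, melody_strategy)
  met <- metrical_accents(stream, params = metrical,
                          anchor_ticks = sc$anchor_ticks)
  mel <- melodic_accents(melody, params = melodic,
                         barline_ticks = function(m) measure_start_tick(sc, m))
  # melodic saliences attach to the sonority at the melody note's onset
  C <- numeric(nrow(stream$sonorities))
  idx <- match(melody$onset_ticks, stream$sonorities$onset_ticks)
  C[idx[!is.na(idx)]] <- mel$C[!is.na(idx)]
  harm <- harmonic_accents(stream, familiarity, hstyle, weights,
                           prepared_counts = prepared_counts,
                           negative = negative)
  prov <- sprintf(
    "accentr %s | style=%s M=%g S=%g k=%g N=%g Pv=%g Ph=%g x=(%g,%g,%g) | familiarity: %s",
    as.character(utils::packageVersion("accentr")), style,
    metrical$M, metrical$S, metrical$k, melodic$N_norm,
    hstyle$P_v, hstyle$P_h, hstyle$x1, hstyle$x2, hstyle$x3,
    familiarity$provenance)
  tab <- accent_table(stream, M = met$M, C = C, Hv = harm$Hv, Hh = harm$Hh,
                      H1 = harm$H1, H2 = harm$H2, provenance = prov)
  structure(list(table = tab, stream = stream, melody = melody, score = sc,
                 melodic_detail = mel, metrical_detail = met,
                 params = list(style = style, metrical = metrical,
                               melodic = melodic, harmonic = hstyle,
                               weights = weights,
                               melody_strategy = melody_strategy),
                 familiarity = familiarity),
            class = "accent_analysis")
}

#' @export
print.accent_analysis <- function(x, ...) {
  tab <- x$table
  cat(sprintf("Immanent accent analysis (%d sonorities, style %s)\n",
              nrow(tab), x$params$style))
  for (cat_name in c("M", "C", "Hv", "Hh", "H1", "H2")) {
    v <- tab[[cat_name]]
    cat(sprintf("  %-3s %3d accents, max salience %.3f\n",
                paste0(cat_name, ":"), sum(v > 0), max(v)))
  }
  invisible(x)
}

#' @export
summary.accent_analysis <- function(object, ...) {
  tab <- object$table
  cats <- c("M", "C", "Hv", "Hh", "H1", "H2")
  stats <- data.frame(
    category = cats,
    n_accents = vapply(cats, function(cc) sum(tab[[cc]] > 0), integer(1)),
    proportion = vapply(cats, function(cc) mean(tab[[cc]] > 0), numeric(1)),
    mean_nonzero = vapply(cats, function(cc) {
      v <- tab[[cc]][tab[[cc]] > 0]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1)),
    max = vapply(cats, function(cc) max(tab[[cc]]), numeric(1)))
  rownames(stats) <- NULL
  out <- list(n_sonorities = nrow(tab), style = object$params$style,
              stats = stats)
  class(out) <- "summary.accent_analysis"
  out
}

#' @export
print.summary.accent_analysis <- function(x, ...) {
  cat(sprintf("Immanent accent analysis: %d sonorities, style %s\n",
              x$n_sonorities, x$style))
  print(x$stats, digits = 3)
  invisible(x)
}

#' @export
as.data.frame.accent_analysis <- function(x, ...) as.data.frame(x$table)

#' Stem plot of accent saliences along the piece
#'
#' @param x an [accent_analysis] object.
#' @param categories which columns to draw.
#' @param ... passed to [graphics::plot].
#' @export
plot.accent_analysis <- function(x, categories = c("M", "C", "H2"), ...) {
  tab <- x$table
  n <- length(categories)
  old <- graphics::par(mfrow = c(n, 1), mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(old))
  for (cc in categories) {
    graphics::plot(tab$onset_wholes, tab[[cc]], type = "h", lwd = 2,
                   ylim = c(0, 5), xlab = "", ylab = cc, ...)
    graphics::points(tab$onset_wholes[tab[[cc]] > 0],
                     tab[[cc]][tab[[cc]] > 0], pch = 16)
    graphics::abline(h = 0, col = "grey")
  }
  invisible(x)
}

#' Analyze a score file end to end
#'
#' Thin file-level wrapper used by the command-line interface: reads the
#' score, runs [accent_analysis], and writes the accent table as CSV and
#' JSON next to a run log. All floating-point output carries six decimals;
#' repeated runs with identical inputs are byte-identical.
#'
#' @param path input score file.
#' @param out_prefix output path prefix (default: input path without
#'   extension); writes `<prefix>.accents.csv` and `<prefix>.accents.json`.
#' @param format,style,familiarity_path,... passed to the readers and
#'   [accent_analysis].
#' @return the [accent_analysis] object, invisibly.
#' @export
analyze_score_file <- function(path, out_prefix = NULL, format = "auto",
                               style = NULL, familiarity_path = NULL, ...) {
  sc <- read_score(path, format)
  fam <- if (!is.null(familiarity_path)) read_familiarity(familiarity_path)
         else default_familiarity()
  fit <- accent_analysis(sc, style = style, familiarity = fam, ...)
  prefix <- out_prefix %||% sub("\\.[A-Za-z]+$", "", path)
  write_accent_table(fit$table, paste0(prefix, ".accents.csv"))
  write_accent_table(fit$table, paste0(prefix, ".accents.json"))
  invisible(fit)
}

#' Package and parameter provenance line
#'
#' @return character vector describing the package version and the default
#'   model parameters, printed and returned invisibly.
#' @export
version_and_provenance <- function() {
  mp <- metrical_params(); lp <- melodic_params()
  lines <- c(
    sprintf("accentr %s", as.character(utils::packageVersion("accentr"))),
    sprintf("metrical: k=%g M=%g S=%g cutoff=%g", mp$k, mp$M, mp$S, mp$cutoff),
    sprintf("melodic: N=%g below_mean=%g falling=%g cutoff=%g",
            lp$N_norm, lp$below_mean_weight, lp$falling_interval_weight,
            lp$cutoff),
    vapply(c("baroque_classical", "romantic", "late_romantic"), function(s) {
      sp <- style_params(s)
      sprintf("style %s: Pv=%g Ph=%g x1=%g x2=%g x3=%g", s, sp$P_v, sp$P_h,
              sp$x1, sp$x2, sp$x3)
    }, character(1)),
    sprintf("default familiarity: %s", default_familiarity()$provenance))
  cat(lines, sep = "\n")
  invisible(lines)
}
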