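#' Footprint factors from normal and experimental hind-paw measurements
#'
#' Three dimensionless gait factors are derived from the print length (PL),
#' first-to-fifth toe spread (TS) and second-to-fourth intermediary toe
#' spread (IT) of the experimental (injured) paw E against the contralateral
#' normal paw N:
#' \deqn{PLF = (NPL - EPL)/EPL,\quad TSF = (ETS - NTS)/NTS,\quad
#'   ITF = (EIT - NIT)/NIT}
#' Lengths are typically in mm, but the factors are ratios so the unit
#' cancels.
#'
#' @param normal,experimental lists or data.frames with numeric elements
#'   \code{PL}, \code{TS}, \code{IT}, all strictly positive and finite;
#'   vectorized over animals.
#' @return A data.frame with columns \code{PLF}, \code{TSF}, \code{ITF}.
#' @examples
#' footprint_factors(list(PL = 30, TS = 20, IT = 10),
#'                   list(PL = 40, TS = 15, IT = 8))
#' @export
footprint_factors <- function(normal, experimental) {
  chk <- function(m, label) {
    for (f in c("PL", "TS", "IT")) {
      v <- m[[f]]
      if (is.null(v) || any(!is.finite(v)) || any(v <= 0))
        stop(label, " measure '", f, "' must be finite and positive")
    }
    m
  }
  n <- chk(normal, "normal")
  e <- chk(experimental, "experimental")
  data.frame(PLF = (n$PL - e$PL) / e$PL,
             TSF = (e$TS - n$TS) / n$TS,
             ITF = (e$IT - n$IT) / n$IT)
}

#' Achilles functional index
#'
#' Linear gait score \code{AFI = 74*PLF + 161*TSF + 48*ITF - 5}; more
#' negative values indicate more serious hindlimb hypomotility. An
#' uninjured paw (all factors zero) scores -5.
#'
#' @param PLF,TSF,ITF footprint factors (see
#'   \code{\link{footprint_factors}}); finite, vectorized.
#' @return Numeric AFI value(s).
#' @examples
#' afi(0, 0, 0)  # -5
#' @export
afi <- function(PLF, TSF, ITF) {
  if (any(!is.finite(PLF)) || any(!is.finite(TSF)) || any(!is.finite(ITF)))
    stop("footprint factors must be finite")
  74 * PLF + 161 * TSF + 48 * ITF - 5
}

#' Normalized grip-strength index
#'
#' Five sequential grip readings per animal: the minimum and maximum are
#' discarded, the middle three order statistics averaged, and the mean
#' normalized by body weight (g/BW).
#'
#' @param readings exactly five finite, positive grip forces in grams.
#' @param body_weight body weight in grams, positive.
#' @return The grip index (g/BW), a single numeric value.
#' @examples
#' grip_index(c(10, 20, 30, 40, 50), 300)  # 0.1
#' @export
grip_index <- function(readings, body_weight) {
  readings <- as.numeric(readings)
  if (length(readings) != 5L)
    stop("exactly five grip readings are required, got ", length(readings))
  if (any(!is.finite(readings)) || any(readings <= 0))
    stop("grip readings must be finite and positive")
  if (!is.finite(body_weight) || body_weight <= 0)
    stop("body weight must be finite and positive")
  mean(sort(readings)[2:4]) / body_weight
}

#' Compute AFI and grip index over a measurement table
#'
#' Appends \code{PLF}, \code{TSF}, \code{ITF}, \code{AFI} (from columns
#' \code{NPL}, \code{EPL}, \code{NTS}, \code{ETS}, \code{NIT}, \code{EIT})
#' and, when grip columns \code{grip1..grip5} and \code{BW} are present,
#' \code{g_BW}, to a per-animal table.
#'
#' @param df data.frame, one row per animal/timepoint.
#' @return The input with result columns appended.
#' @export
afi_table <- function(df) {
  need <- c("NPL", "EPL", "NTS", "ETS", "NIT", "EIT")
  if (!all(need %in% names(df)))
    stop("measurement table is missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  ff <- footprint_factors(list(PL = df$NPL, TS = df$NTS, IT = df$NIT),
                          list(PL = df$EPL, TS = df$ETS, IT = df$EIT))
  df$PLF <- ff$PLF
  df$TSF <- ff$TSF
  df$ITF <- ff$ITF
  df$AFI <- afi(ff$PLF, ff$TSF, ff$ITF)
  grip_cols <- paste0("grip", 1:5)
  if (all(c(grip_cols, "BW") %in% names(df))) {
    df$g_BW <- vapply(seq_len(nrow(df)), function(i)
      grip_index(as.numeric(df[i, grip_cols]), df$BW[i]), numeric(1))
  }
  df
}

#' Read / write footprint-and-grip measurement CSVs
#'
#' @param path CSV path.
#' @return \code{read_footprint_csv}: a data.frame.
#' @export
read_footprint_csv <- function(path) {
  if (!file.exists(path)) stop("footprint file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_footprint_csv
#' @param df data.frame to write.
#' @export
write_footprint_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
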