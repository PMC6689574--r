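# Assemble per-individual attribute records at 0/24/48 h into the long-format
# table of colour shifts the models consume. Sign convention: later minus
# earlier, so a positive lightness delta means the fish got lighter.

.shift_time_points <- c(0, 24, 48)

# signed shortest angular difference, result in (-180, 180]
.hue_delta <- function(later, earlier) {
  d <- (later - earlier + 180) %% 360 - 180
  d[d == -180] <- 180
  d
}

#' Compute colour shifts between time points
#'
#' Takes wide attribute records (one row per unit and time point with
#' columns `L`, `a`, `b`, `h`, `C`) and returns the long shift table: one
#' row per unit, interval (0-24, 0-48, 24-48 h) and attribute, with
#' `delta = later - earlier`. Hue deltas use the signed shortest angular
#' difference in (-180, 180\], so a move from 350 to 10 degrees is +20, not
#' -340. Units missing any of the three time points are dropped with a
#' warning and listed in the `dropped` attribute of the result.
#'
#' @param records Data frame with columns `individual_id`, `time_h` and at
#'   least one of `L`, `a`, `b`, `h`, `C`; optional `unit_id`, `line`,
#'   `treatment` are carried through (units default to
#'   `individual_id` x `treatment`).
#' @param attributes Attribute columns to difference (default all present
#'   among L, a, b, h, C).
#' @return Long data frame `unit_id, individual_id, line, treatment,
#'   interval, time_h, attribute, delta` with attribute `dropped` (character
#'   vector of incomplete units).
#' @export
compute_shifts <- function(records,
                           attributes = intersect(c("L", "a", "b", "h", "C"),
                                                  names(records))) {
  if (!all(c("individual_id", "time_h") %in% names(records))) {
    stop("records must have columns individual_id and time_h")
  }
  # long value/attribute records (e.g. from generate_attribute_records):
  # pivot each attribute into its own column first
  if (all(c("value", "attribute") %in% names(records)) && !length(attributes)) {
    idcols <- intersect(c("unit_id", "individual_id", "line", "treatment", "time_h"),
                        names(records))
    base <- unique(records[, idcols, drop = FALSE])
    bkey <- do.call(paste, base[idcols])
    for (at in unique(records$attribute)) {
      sub <- records[records$attribute == at, , drop = FALSE]
      base[[at]] <- sub$value[match(bkey, do.call(paste, sub[idcols]))]
    }
    records <- base
    attributes <- setdiff(names(base), idcols)
  }
  if (!length(attributes)) stop("no attribute columns found to difference")
  if (!all(records$time_h %in% .shift_time_points)) {
    stop("time_h values must be in {", paste(.shift_time_points, collapse = ", "), "}")
  }
  if (is.null(records$treatment)) records$treatment <- "all"
  if (is.null(records$line)) records$line <- NA
  if (is.null(records$unit_id)) {
    records$unit_id <- paste(records$individual_id, records$treatment, sep = ".")
  }
  key <- paste(records$unit_id, records$time_h)
  if (anyDuplicated(key)) {
    stop("duplicate (unit, time) records: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }

  units <- unique(records[, c("unit_id", "individual_id", "line", "treatment")])
  have <- tapply(records$time_h, records$unit_id,
                 function(t) all(.shift_time_points %in% t))
  dropped <- names(have)[!have]
  if (length(dropped)) {
    warning("dropping ", length(dropped),
            " unit(s) missing a time point: ", paste(dropped, collapse = ", "))
    units <- units[!units$unit_id %in% dropped, , drop = FALSE]
  }
  if (!nrow(units)) {
    out <- data.frame(unit_id = character(), individual_id = character(),
                      line = character(), treatment = character(),
                      interval = factor(character(), levels = levels(.INTERVALS$interval)),
                      time_h = numeric(), attribute = character(),
                      delta = numeric())
    attr(out, "dropped") <- dropped
    return(out)
  }

  wide <- lapply(.shift_time_points, function(t) {
    rows <- records[records$time_h == t, , drop = FALSE]
    rows[match(units$unit_id, rows$unit_id), attributes, drop = FALSE]
  })
  names(wide) <- as.character(.shift_time_points)

  out <- do.call(rbind, lapply(seq_len(nrow(.INTERVALS)), function(k) {
    from <- as.character(.INTERVALS$from_h[k])
    to <- as.character(.INTERVALS$to_h[k])
    do.call(rbind, lapply(attributes, function(at) {
      later <- wide[[to]][[at]]
      earlier <- wide[[from]][[at]]
      delta <- if (at == "h") .hue_delta(later, earlier) else later - earlier
      data.frame(units,
                 interval = .INTERVALS$interval[k],
                 time_h = .INTERVALS$time_h[k],
                 attribute = at, delta = delta)
    }))
  }))
  out <- out[order(out$unit_id, out$attribute, out$interval), ]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}
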