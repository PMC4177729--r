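# The RAG "pizza" plot: weight-proportional circular report, rendered as
# deterministic standalone SVG (a pure function of the plot spec).

.RAG_PALETTE <- c(red = "#d7191c", amber = "#fdae61", green = "#1a9641")

#' Build the pizza-plot specification for a result
#'
#' Each matched category becomes one circular sector whose angle is
#' proportional to its group weight: `angle = 360 * weight / sum(weights)`,
#' so a red lesion always draws a larger slice than an amber or green
#' one. Segments are ordered red, then amber, then green, alphabetically
#' within a group; start angles accumulate clockwise from zero at twelve
#' o'clock.
#'
#' @param result A [RagResult-class] or [CombinedReport-class] with at
#'   least one matched category. An unscorable result raises a
#'   validation error: there is nothing to plot.
#' @return A [PizzaPlotSpec-class].
#' @export
#' @examples
#' kb <- buildDefaultKB()
#' res <- scoreAberrations(kb, list(aberration("deletion", "del(17p)"),
#'                                  aberration("trisomy", 9, method = "karyotype")))
#' plotSegments(buildPlotSpec(res))
buildPlotSpec <- function(result) {
  if (is(result, "CombinedReport")) result <- result@rag
  stopifnot(is(result, "RagResult"))
  if (!length(result@matches))
    ragValidationError("result is unscorable (no matched categories); ",
                       "no pizza plot can be drawn")
  seg <- data.frame(
    category = vapply(result@matches, `[[`, character(1), "category"),
    group = vapply(result@matches, `[[`, character(1), "group"),
    weight = vapply(result@matches, `[[`, numeric(1), "weight"),
    stringsAsFactors = FALSE)
  ord <- order(match(seg$group, .RAG_GROUPS), seg$category)
  seg <- seg[ord, , drop = FALSE]
  seg$angle <- 360 * seg$weight / sum(seg$weight)
  seg$start <- cumsum(c(0, seg$angle[-nrow(seg)]))
  rownames(seg) <- NULL
  new("PizzaPlotSpec", segments = seg, score = result@score,
      band = result@band)
}

# Point on the circle at `deg` degrees clockwise from twelve o'clock.
.clockPoint <- function(cx, cy, r, deg) {
  rad <- deg * pi / 180
  c(x = cx + r * sin(rad), y = cy - r * cos(rad))
}

.sectorPath <- function(cx, cy, r, start, angle) {
  if (angle >= 360 - 1e-9) {
    p0 <- .clockPoint(cx, cy, r, 0); p1 <- .clockPoint(cx, cy, r, 180)
    return(sprintf("M %s %s A %s %s 0 1 1 %s %s A %s %s 0 1 1 %s %s Z",
                   fmtNum(p0["x"]), fmtNum(p0["y"]), fmtNum(r), fmtNum(r),
                   fmtNum(p1["x"]), fmtNum(p1["y"]), fmtNum(r), fmtNum(r),
                   fmtNum(p0["x"]), fmtNum(p0["y"])))
  }
  a <- .clockPoint(cx, cy, r, start)
  b <- .clockPoint(cx, cy, r, start + angle)
  sprintf("M %s %s L %s %s A %s %s 0 %d 1 %s %s Z",
          fmtNum(cx), fmtNum(cy), fmtNum(a["x"]), fmtNum(a["y"]),
          fmtNum(r), fmtNum(r), as.integer(angle > 180),
          fmtNum(b["x"]), fmtNum(b["y"]))
}

#' Render a pizza-plot specification as standalone SVG
#'
#' Writes an SVG 1.1 document with one filled sector `<path>` per
#' segment (fixed colour-blind-safe palette: red `#d7191c`, amber
#' `#fdae61`, green `#1a9641`), category labels, and the RAG score and
#' band centred in a donut hole. Output is a pure function of the spec —
#' no timestamps, no random ids — so rendering the same spec twice gives
#' byte-identical files. Each sector carries `data-category`,
#' `data-group`, `data-start` and `data-angle` attributes for machine
#' re-reading.
#'
#' @param spec A [PizzaPlotSpec-class].
#' @param path Output file path (`.svg`).
#' @return `path`, invisibly.
#' @export
renderSvg <- function(spec, path) {
  stopifnot(is(spec, "PizzaPlotSpec"))
  if (!dir.exists(dirname(path)))
    ragIOError("output directory does not exist: ", dirname(path))
  cx <- 210; cy <- 210; r <- 170; hole <- 72
  seg <- spec@segments
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" ',
           'width="420" height="460" viewBox="0 0 420 460">'),
    '<rect width="420" height="460" fill="#ffffff"/>')
  for (i in seq_len(nrow(seg))) {
    lines <- c(lines, sprintf(
      '<path d="%s" fill="%s" stroke="#ffffff" stroke-width="2" data-category="%s" data-group="%s" data-start="%s" data-angle="%s"/>',
      .sectorPath(cx, cy, r, seg$start[i], seg$angle[i]),
      .RAG_PALETTE[[seg$group[i]]], xmlEscape(seg$category[i]),
      seg$group[i], fmtNum(seg$start[i]), fmtNum(seg$angle[i])))
  }
  lines <- c(lines, sprintf(
    '<circle cx="%d" cy="%d" r="%d" fill="#ffffff"/>', cx, cy, hole))
  # category labels at the mid-angle of each sector
  for (i in seq_len(nrow(seg))) {
    mid <- seg$start[i] + seg$angle[i] / 2
    p <- .clockPoint(cx, cy, (r + hole) / 2 + 18, mid)
    lines <- c(lines, sprintf(
      '<text x="%s" y="%s" font-family="sans-serif" font-size="11" text-anchor="middle" fill="#000000">%s</text>',
      fmtNum(p["x"]), fmtNum(p["y"]), xmlEscape(seg$category[i])))
  }
  lines <- c(lines,
    sprintf(paste0('<text x="%d" y="%d" font-family="sans-serif" ',
                   'font-size="30" font-weight="bold" text-anchor="middle" ',
                   'fill="#000000">%s</text>'),
            cx, cy + 2, fmtNum(spec@score, 2)),
    sprintf(paste0('<text x="%d" y="%d" font-family="sans-serif" ',
                   'font-size="13" text-anchor="middle" ',
                   'fill="#000000">%s</text>'),
            cx, cy + 26, xmlEscape(gsub("_", "-", spec@band))),
    sprintf(paste0('<text x="%d" y="440" font-family="sans-serif" ',
                   'font-size="12" text-anchor="middle" fill="#000000">',
                   'RAG score (mean of red=3, amber=2, green=1)</text>'), cx),
    '</svg>')
  ok <- try(writeLines(lines, path, useBytes = TRUE), silent = TRUE)
  if (inherits(ok, "try-error")) ragIOError("cannot write SVG: ", path)
  invisible(path)
}
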