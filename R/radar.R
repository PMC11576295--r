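#' Chart style configuration
#'
#' Geometry-free aesthetics for the radar charts, kept in one place so
#' layouts are pure geometry and tests compare coordinates, not colors.
#'
#' @param ... Overrides of the defaults.
#' @return Named list.
#' @export
chart_style <- function(...) {
  utils::modifyList(list(
    width = 800, height = 800, margin = 60,
    stroke = "#333333", ray = "#2c5f8a", grid = "#bbbbbb",
    circle_fill = "none", font = "sans-serif", font_size = 12
  ), list(...))
}

#' Item-level radar layout
#'
#' Items of one facet occupy one contiguous angular sector (sector widths
#' proportional to item counts); items are evenly spaced within their
#' sector. The radial coordinate is linear in the center distance; dotted
#' grid rings sit at fixed cd increments. Every second item carries an
#' `alt` flag so renderers can alternate ray lengths for legibility.
#'
#' @param items Data frame with `item_id`, `cd` and (optionally) `facet`
#'   columns, e.g. one instrument's block of an `ipv_nested` item table.
#' @param ring_step Grid ring spacing in cd units (default 0.1).
#' @param style A [chart_style()].
#' @return Object of class `ipv_item_layout`: `items` (`item_id`, `facet`,
#'   `angle` in radians, `radial` = cd, `alt`), `rings` (cd values of grid
#'   rings), `sectors` (facet -> angular interval), `cd_max`, `style`.
#' @export
layout_item_chart <- function(items, ring_step = 0.1, style = chart_style()) {
  stopifnot(nrow(items) >= 1L, !is.null(items$cd))
  if (any(items$cd < 0)) stop("radial positions require cd >= 0")
  facet <- if (is.null(items$facet)) rep("pool", nrow(items)) else items$facet
  facs <- unique(facet)
  counts <- vapply(facs, function(f) sum(facet == f), integer(1))
  sec_end <- 2 * pi * cumsum(counts) / sum(counts)
  sec_start <- c(0, sec_end[-length(sec_end)])
  angle <- numeric(nrow(items))
  for (j in seq_along(facs)) {
    sel <- which(facet == facs[j])
    # even spacing inside the sector, half-step inset at both edges
    width <- sec_end[j] - sec_start[j]
    angle[sel] <- sec_start[j] + width * (seq_along(sel) - 0.5) / length(sel)
  }
  cd_max <- max(items$cd, ring_step)
  rings <- seq(ring_step, ceiling(cd_max / ring_step) * ring_step,
               by = ring_step)
  structure(list(
    items = data.frame(item_id = items$item_id, facet = facet,
                       angle = angle, radial = items$cd,
                       alt = seq_len(nrow(items)) %% 2L == 0L,
                       stringsAsFactors = FALSE),
    rings = rings,
    sectors = data.frame(facet = facs, start = sec_start, end = sec_end,
                         stringsAsFactors = FALSE),
    cd_max = max(rings), style = style), class = "ipv_item_layout")
}

#' Nested (scale-level) chart layout
#'
#' Each instrument is a circle whose center sits at a distance proportional
#' to the instrument's aggregate center distance from the chart center, so
#' the instrument closest to the construct core is nearest the middle.
#' Instruments are spread at evenly spaced angles (deterministic; circles
#' can never collide in angle). Facet markers sit inside their instrument's
#' circle at a radius proportional to the facet's aggregate cd *relative to
#' the largest facet cd of that instrument* -- facet positions are only
#' interpretable within their own circle. Latent correlations are annotated
#' between every pair of instrument circles.
#'
#' @param result An `ipv_nested` from [run_nested_ipv()], or a list with
#'   `pool_summaries` and `latent_corr` of the same shape.
#' @param circle_radius Instrument circle radius as a fraction of the chart
#'   radius (default 0.22).
#' @param style A [chart_style()].
#' @return Object of class `ipv_nested_layout`: `instruments` (`pool_id`,
#'   `aggregate_cd`, `angle`, `radial` in cd units, `x`, `y`, `r` in
#'   normalized chart units), `facets` (marker coordinates inside their
#'   circle), `labels` (pairwise correlation annotations with midpoint
#'   coordinates), `style`.
#' @export
layout_nested_chart <- function(result, circle_radius = 0.22,
                                style = chart_style()) {
  ps <- result$pool_summaries
  inst <- ps[ps$level == "instrument", ]
  inst <- inst[order(inst$aggregate_cd), ]
  k <- nrow(inst)
  # floor at 0: a pool whose raw aggregate is negative sits at the center
  rad_cd <- pmax(inst$aggregate_cd, 0)
  scale_cd <- max(rad_cd, 1e-9)
  # normalized chart units: center offsets occupy [0, 1 - circle_radius]
  rho <- (1 - circle_radius - 0.05) * rad_cd / scale_cd
  theta <- pi / 2 + 2 * pi * (seq_len(k) - 1) / k
  instruments <- data.frame(
    pool_id = inst$pool_id, aggregate_cd = inst$aggregate_cd,
    angle = theta, radial = rad_cd,
    x = rho * cos(theta), y = rho * sin(theta), r = circle_radius,
    stringsAsFactors = FALSE)
  fac <- ps[ps$level == "facet", ]
  facets <- NULL
  if (nrow(fac)) {
    fac$instrument <- sub("\\..*$", "", fac$pool_id)
    rows <- lapply(split(fac, fac$instrument), function(ff) {
      ff <- ff[order(ff$aggregate_cd), ]
      ci <- instruments[instruments$pool_id == ff$instrument[1], ]
      if (!nrow(ci)) return(NULL)
      m <- nrow(ff)
      fr <- pmax(ff$aggregate_cd, 0)
      fs <- max(fr, 1e-9)
      ang <- pi / 2 + 2 * pi * (seq_len(m) - 1) / m
      data.frame(pool_id = ff$pool_id, instrument = ff$instrument,
                 aggregate_cd = ff$aggregate_cd,
                 x = ci$x + 0.8 * ci$r * (fr / fs) * cos(ang),
                 y = ci$y + 0.8 * ci$r * (fr / fs) * sin(ang),
                 stringsAsFactors = FALSE)
    })
    facets <- do.call(rbind, rows)
    rownames(facets) <- NULL
  }
  labels <- NULL
  if (k >= 2L) {
    pr <- utils::combn(seq_len(k), 2)
    lc <- result$latent_corr
    labels <- data.frame(
      a = instruments$pool_id[pr[1, ]], b = instruments$pool_id[pr[2, ]],
      value = lc[cbind(instruments$pool_id[pr[1, ]],
                       instruments$pool_id[pr[2, ]])],
      x = (instruments$x[pr[1, ]] + instruments$x[pr[2, ]]) / 2,
      y = (instruments$y[pr[1, ]] + instruments$y[pr[2, ]]) / 2,
      stringsAsFactors = FALSE)
  }
  structure(list(instruments = instruments, facets = facets,
                 labels = labels, style = style),
            class = "ipv_nested_layout")
}

## SVG rendering -------------------------------------------------------------

svg_num <- function(x) sprintf("%.3f", x)

svg_open <- function(style) {
  c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
            style$width, style$height, style$width, style$height),
    sprintf('<rect width="%d" height="%d" fill="#ffffff"/>',
            style$width, style$height))
}

# map normalized [-1, 1] coordinates into pixel space (y axis flipped)
svg_px <- function(x, y, style) {
  half <- min(style$width, style$height) / 2 - style$margin
  list(x = style$width / 2 + half * x, y = style$height / 2 - half * y)
}

#' Render a chart layout to a file
#'
#' SVG output is plain text generated from the layout geometry with fixed
#' 3-decimal coordinate formatting: identical layouts render to identical
#' bytes. PNG goes through the `grDevices::png()` device (raster; not
#' byte-stable across platforms).
#'
#' @param layout An `ipv_item_layout` or `ipv_nested_layout`.
#' @param path Output file path.
#' @param format `"svg"` (default) or `"png"`.
#' @return `path`, invisibly.
#' @export
render_chart <- function(layout, path, format = c("svg", "png")) {
  format <- match.arg(format)
  if (format == "svg") {
    lines <- svg_lines(layout)
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
  } else {
    grDevices::png(path, width = layout$style$width,
                   height = layout$style$height)
    on.exit(grDevices::dev.off())
    plot_layout(layout)
  }
  invisible(path)
}

svg_lines <- function(layout) UseMethod("svg_lines")

#' @export
svg_lines.ipv_item_layout <- function(layout) {
  st <- layout$style
  out <- svg_open(st)
  unit <- 1 / layout$cd_max
  for (rr in layout$rings) {
    c0 <- svg_px(0, 0, st)
    half <- min(st$width, st$height) / 2 - st$margin
    out <- c(out, sprintf(
      '<circle cx="%s" cy="%s" r="%s" fill="none" stroke="%s" stroke-dasharray="4 4"/>',
      svg_num(c0$x), svg_num(c0$y), svg_num(half * rr * unit), st$grid))
    lab <- svg_px(0, rr * unit, st)
    out <- c(out, sprintf(
      '<text x="%s" y="%s" font-family="%s" font-size="%d" fill="%s">%s</text>',
      svg_num(lab$x + 4), svg_num(lab$y - 2), st$font, st$font_size, st$grid,
      svg_num(rr)))
  }
  it <- layout$items
  for (i in seq_len(nrow(it))) {
    # alternating extra ray length for visual separation (style only)
    extra <- if (it$alt[i]) 0.03 else 0
    r <- it$radial[i] * unit
    tip <- svg_px((r + extra) * cos(it$angle[i]),
                  (r + extra) * sin(it$angle[i]), st)
    c0 <- svg_px(0, 0, st)
    mk <- svg_px(r * cos(it$angle[i]), r * sin(it$angle[i]), st)
    out <- c(out,
      sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s"/>',
              svg_num(c0$x), svg_num(c0$y), svg_num(tip$x), svg_num(tip$y),
              st$ray),
      sprintf('<circle cx="%s" cy="%s" r="3" fill="%s"/>',
              svg_num(mk$x), svg_num(mk$y), st$ray))
    if (nzchar(it$item_id[i])) {
      lab <- svg_px((r + extra + 0.05) * cos(it$angle[i]),
                    (r + extra + 0.05) * sin(it$angle[i]), st)
      out <- c(out, sprintf(
        '<text x="%s" y="%s" font-family="%s" font-size="%d" text-anchor="middle">%s</text>',
        svg_num(lab$x), svg_num(lab$y), st$font, st$font_size, it$item_id[i]))
    }
  }
  c(out, "</svg>")
}

#' @export
svg_lines.ipv_nested_layout <- function(layout) {
  st <- layout$style
  out <- svg_open(st)
  c0 <- svg_px(0, 0, st)
  half <- min(st$width, st$height) / 2 - st$margin
  out <- c(out, sprintf('<circle cx="%s" cy="%s" r="4" fill="%s"/>',
                        svg_num(c0$x), svg_num(c0$y), st$stroke))
  ins <- layout$instruments
  for (i in seq_len(nrow(ins))) {
    ct <- svg_px(ins$x[i], ins$y[i], st)
    out <- c(out,
      sprintf('<circle cx="%s" cy="%s" r="%s" fill="%s" stroke="%s" stroke-width="2"/>',
              svg_num(ct$x), svg_num(ct$y), svg_num(half * ins$r[i]),
              st$circle_fill, st$ray))
    if (nzchar(ins$pool_id[i]))
      out <- c(out, sprintf(
        '<text x="%s" y="%s" font-family="%s" font-size="%d" text-anchor="middle" font-weight="bold">%s</text>',
        svg_num(ct$x), svg_num(ct$y - half * ins$r[i] - 6), st$font,
        st$font_size, ins$pool_id[i]))
  }
  if (!is.null(layout$facets)) {
    fc <- layout$facets
    for (i in seq_len(nrow(fc))) {
      ct <- svg_px(fc$x[i], fc$y[i], st)
      out <- c(out,
        sprintf('<circle cx="%s" cy="%s" r="4" fill="%s"/>',
                svg_num(ct$x), svg_num(ct$y), st$stroke),
        if (nzchar(fc$pool_id[i])) sprintf(
          '<text x="%s" y="%s" font-family="%s" font-size="%d" text-anchor="middle">%s</text>',
          svg_num(ct$x), svg_num(ct$y + 14), st$font, st$font_size - 2,
          sub("^.*\\.", "", fc$pool_id[i])))
    }
  }
  if (!is.null(layout$labels)) {
    lb <- layout$labels
    for (i in seq_len(nrow(lb))) {
      ct <- svg_px(lb$x[i], lb$y[i], st)
      out <- c(out, sprintf(
        '<text x="%s" y="%s" font-family="%s" font-size="%d" text-anchor="middle" fill="%s">%s</text>',
        svg_num(ct$x), svg_num(ct$y), st$font, st$font_size, st$stroke,
        sprintf("%.2f", lb$value[i])))
    }
  }
  c(out, "</svg>")
}

plot_layout <- function(layout) UseMethod("plot_layout")

#' @export
plot_layout.ipv_item_layout <- function(layout) {
  unit <- 1 / layout$cd_max
  graphics::plot.new()
  graphics::plot.window(c(-1.2, 1.2), c(-1.2, 1.2), asp = 1)
  tt <- seq(0, 2 * pi, length.out = 181)
  for (rr in layout$rings)
    graphics::lines(rr * unit * cos(tt), rr * unit * sin(tt),
                    lty = 3, col = layout$style$grid)
  it <- layout$items
  graphics::segments(0, 0, it$radial * unit * cos(it$angle),
                     it$radial * unit * sin(it$angle), col = layout$style$ray)
  graphics::points(it$radial * unit * cos(it$angle),
                   it$radial * unit * sin(it$angle), pch = 16,
                   col = layout$style$ray)
  graphics::text(1.08 * it$radial * unit * cos(it$angle),
                 1.08 * it$radial * unit * sin(it$angle), it$item_id, cex = 0.7)
}

#' @export
plot_layout.ipv_nested_layout <- function(layout) {
  graphics::plot.new()
  graphics::plot.window(c(-1.2, 1.2), c(-1.2, 1.2), asp = 1)
  graphics::points(0, 0, pch = 16)
  tt <- seq(0, 2 * pi, length.out = 181)
  ins <- layout$instruments
  for (i in seq_len(nrow(ins))) {
    graphics::lines(ins$x[i] + ins$r[i] * cos(tt),
                    ins$y[i] + ins$r[i] * sin(tt), col = layout$style$ray)
    graphics::text(ins$x[i], ins$y[i] + ins$r[i] + 0.05, ins$pool_id[i])
  }
  if (!is.null(layout$facets))
    graphics::points(layout$facets$x, layout$facets$y, pch = 16, cex = 0.7)
  if (!is.null(layout$labels))
    graphics::text(layout$labels$x, layout$labels$y,
                   sprintf("%.2f", layout$labels$value), cex = 0.8)
}
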