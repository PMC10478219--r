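#' Read and write lattice grids
#'
#' The canonical interchange format is a plain-text integer matrix
#' with site codes `{0, 2, +1, -1}`, one row per line, preceded by a
#' one-line header `# cpim L=<int> sweep=<int> mode=<cpim|pure_ising>`.
#' Grids can also be exported as PGM (P2) with the gray mapping
#' `{0 -> 0, 2 -> 85, -1 -> 170, +1 -> 255}` or as PNG using the
#' state palette (vacant white, undifferentiated black, `+1` magenta,
#' `-1` green); both image formats round-trip through [read_grid()].
#'
#' @param path File path; format is inferred from the extension
#'   (`.pgm`, `.png`, anything else is text).
#' @return `read_grid()` returns a `cpim_lattice`.
#' @name grid_io
NULL

state_palette <- function() {
  # columns: r, g, b per code
  rbind("0" = c(1, 1, 1), "2" = c(0, 0, 0),
        "1" = c(1, 0, 1), "-1" = c(0, 1, 0))
}

pgm_levels <- c("0" = 0L, "2" = 85L, "-1" = 170L, "1" = 255L)

#' @rdname grid_io
#' @export
read_grid <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") return(read_grid_pgm(path))
  if (ext == "png") return(read_grid_png(path))
  lines <- readLines(path)
  if (length(lines) == 0)
    abort("empty grid file.", class = "cpim_parse_error")
  meta <- list(sweep = 0L, mode = "cpim")
  start <- 1L
  if (grepl("^#", lines[1])) {
    h <- lines[1]
    grab <- function(key) {
      m <- regmatches(h, regexec(paste0(key, "=([A-Za-z0-9_]+)"), h))[[1]]
      if (length(m) == 2) m[2] else NA
    }
    if (!is.na(grab("sweep"))) meta$sweep <- as.integer(grab("sweep"))
    if (!is.na(grab("mode"))) meta$mode <- grab("mode")
    start <- 2L
  }
  body <- lines[start:length(lines)]
  body <- body[nzchar(trimws(body))]
  rows <- lapply(seq_along(body), function(k) {
    v <- suppressWarnings(as.integer(strsplit(trimws(body[k]), "\\s+")[[1]]))
    bad <- is.na(v) | !(v %in% c(0L, 2L, 1L, -1L))
    if (any(bad))
      abort(sprintf("illegal site code on line %d of %s",
                    k + start - 1L, path),
            class = "cpim_parse_error")
    v
  })
  if (length(unique(lengths(rows))) != 1)
    abort("ragged rows in grid file.", class = "cpim_parse_error")
  g <- do.call(rbind, rows)
  new_lattice(g, mode = meta$mode, sweep = meta$sweep,
              boundary = if (meta$mode == "pure_ising") "periodic" else "open")
}

read_grid_pgm <- function(path) {
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (toks[1] != "P2")
    abort("only plain (P2) PGM is supported.", class = "cpim_parse_error")
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  vals <- as.integer(toks[-(1:4)])
  if (length(vals) != w * h)
    abort("PGM pixel count does not match header.",
          class = "cpim_parse_error")
  codes <- as.integer(names(pgm_levels))[match(vals, pgm_levels)]
  if (any(is.na(codes)))
    abort("PGM gray level outside the state mapping.",
          class = "cpim_parse_error")
  new_lattice(matrix(codes, nrow = h, ncol = w, byrow = TRUE))
}

read_grid_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  pal <- state_palette()
  codes <- as.integer(rownames(pal))
  # nearest palette colour per pixel
  d <- sapply(seq_len(nrow(pal)), function(k)
    (img[, , 1] - pal[k, 1])^2 + (img[, , 2] - pal[k, 2])^2 +
      (img[, , 3] - pal[k, 3])^2)
  g <- matrix(codes[max.col(-d)], dim(img)[1], dim(img)[2])
  new_lattice(g)
}

#' @rdname grid_io
#' @param state A `cpim_lattice` (or code matrix).
#' @param format `"text"`, `"pgm"` or `"png"`; default inferred from
#'   the extension.
#' @export
write_grid <- function(state, path, format = NULL) {
  format <- format %||% switch(tolower(tools::file_ext(path)),
                               pgm = "pgm", png = "png", "text")
  at <- lattice_attrs(state)
  g <- unclass(state); attributes(g) <- list(dim = dim(g))
  if (format == "text") {
    header <- sprintf("# cpim L=%d sweep=%d mode=%s", nrow(g), at$sweep,
                      at$mode)
    writeLines(c(header, apply(g, 1, paste, collapse = " ")), path)
  } else if (format == "pgm") {
    vals <- pgm_levels[as.character(g)]
    lines <- c("P2", sprintf("%d %d", ncol(g), nrow(g)), "255",
               apply(matrix(vals, nrow(g), ncol(g)), 1, paste,
                     collapse = " "))
    writeLines(lines, path)
  } else if (format == "png") {
    pal <- state_palette()
    idx <- match(as.character(g), rownames(pal))
    img <- array(0, c(nrow(g), ncol(g), 3))
    for (k in 1:3) img[, , k] <- matrix(pal[idx, k], nrow(g), ncol(g))
    png::writePNG(img, path)
  } else abort("unknown grid format.", class = "cpim_usage_error")
  invisible(path)
}

#' Deterministic test-pattern generator
#'
#' Builds two-state grids with known structure, standing in for
#' binarized colony images: exact checkerboards and stripes, iid
#' random fields, half-plane domains, circular mosaics of same-state
#' patches with a tunable characteristic scale (thresholded smoothed
#' Gaussian random field, calibrated so the fitted sACF length
#' constant approximates `scale`), and colonies of radial segregating
#' sectors.
#'
#' @param kind One of `"checkerboard"`, `"iid_random"`, `"stripes"`,
#'   `"two_domain"`, `"disk_mosaic"`, `"sectored_colony"`.
#' @param size Grid side in sites.
#' @param width Stripe width (stripes only).
#' @param scale Characteristic patch scale in sites (disk_mosaic).
#' @param n_sectors Number of radial sectors (sectored_colony).
#' @param seed RNG seed; the output is deterministic given the seed.
#' @return A `cpim_lattice` with values in `{+1, -1}` (plus `0`
#'   outside the disk for the circular kinds).
#' @examples
#' table(make_fixture("checkerboard", 8))
#' @export
make_fixture <- function(kind = c("checkerboard", "iid_random", "stripes",
                                  "two_domain", "disk_mosaic",
                                  "sectored_colony"),
                         size, width = 4, scale = 10, n_sectors = 8,
                         seed = 1) {
  kind <- match.arg(kind)
  set.seed(seed)
  n <- as.integer(size)
  i <- matrix(seq_len(n), n, n)
  j <- matrix(rep(seq_len(n), each = n), n, n)
  g <- switch(kind,
    checkerboard = ifelse((i + j) %% 2 == 0, 1L, -1L),
    iid_random = matrix(sample(c(-1L, 1L), n * n, replace = TRUE), n, n),
    stripes = ifelse(((j - 1) %/% width) %% 2 == 0, 1L, -1L),
    two_domain = ifelse(j <= n / 2, 1L, -1L),
    disk_mosaic = {
      sk <- scale / 1.75  # kernel width calibrated to the fitted length
      z <- matrix(rnorm(n * n), n, n)
      d1 <- pmin(0:(n - 1), n - (0:(n - 1)))
      ker <- exp(-outer(d1^2, d1^2, `+`) / (2 * sk^2))
      sm <- Re(fft(fft(z) * fft(ker / sum(ker)), inverse = TRUE)) / n^2
      fld <- ifelse(sm >= median(sm), 1L, -1L)
      ctr <- (n + 1) / 2
      disk <- (i - ctr)^2 + (j - ctr)^2 <= (n / 2 - 1)^2
      out <- matrix(0L, n, n); out[disk] <- fld[disk]
      out
    },
    sectored_colony = {
      ctr <- (n + 1) / 2
      disk <- (i - ctr)^2 + (j - ctr)^2 <= (n / 2 - 1)^2
      theta <- atan2(j - ctr, i - ctr)
      cuts <- sort(runif(n_sectors, -pi, pi))
      sec <- findInterval(theta, cuts) %% n_sectors
      states <- sample(c(-1L, 1L), n_sectors, replace = TRUE)
      # ensure both states occur
      if (length(unique(states)) == 1) states[1] <- -states[1]
      out <- matrix(0L, n, n)
      out[disk] <- states[sec[disk] + 1L]
      out
    })
  new_lattice(g, mode = "fixture")
}
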