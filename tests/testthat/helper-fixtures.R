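# Shared fixtures: small sequences built in code, a byte-level DICOM writer
# (independent of the package's reader), and lazily cached benchmark
# ensembles reused across test files.

# tiny sequence whose per-frame ROI means are exactly `means`
seq_from_means <- function(means, rows = 6, cols = 6, dt = 1 / 6,
                           spacing = 0.03, modality = "DSA") {
  fr <- array(rep(means, times = rows * cols), c(length(means), rows, cols))
  image_sequence(fr, dt, spacing, modality)
}

whole_roi <- function(seq, label = "") {
  d <- dim(seq$frames)
  roi(0, d[2], 0, d[3], label)
}

# minimal Explicit-VR little-endian multi-frame DICOM, written byte-by-byte
# from the standard's encoding rules (not via the package)
write_minimal_dicom <- function(path, frames, frame_time_ms, spacing_mm) {
  u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
  str_el <- function(g, e, vr, s) {
    p <- charToRaw(s)
    if (length(p) %% 2 == 1) p <- c(p, charToRaw(" "))
    c(u16(g), u16(e), charToRaw(vr), u16(length(p)), p)
  }
  us_el <- function(g, e, v) c(u16(g), u16(e), charToRaw("US"), u16(2L), u16(v))
  nf <- dim(frames)[1]; rows <- dim(frames)[2]; cols <- dim(frames)[3]
  px <- integer(0)
  for (i in seq_len(nf)) px <- c(px, as.integer(t(frames[i, , ])))  # row-major
  pxr <- writeBin(px, raw(), size = 2, endian = "little")
  body <- c(
    str_el(0x0008, 0x0060, "CS", "XA"),
    str_el(0x0018, 0x1063, "DS", format(frame_time_ms)),
    us_el(0x0028, 0x0002, 1L),
    str_el(0x0028, 0x0004, "CS", "MONOCHROME2"),
    str_el(0x0028, 0x0008, "IS", as.character(nf)),
    us_el(0x0028, 0x0010, rows),
    us_el(0x0028, 0x0011, cols),
    str_el(0x0028, 0x0030, "DS", paste(spacing_mm, spacing_mm, sep = "\\")),
    us_el(0x0028, 0x0100, 16L),
    us_el(0x0028, 0x0101, 16L),
    us_el(0x0028, 0x0102, 15L),
    us_el(0x0028, 0x0103, 0L),
    c(u16(0x7fe0), u16(0x0010), charToRaw("OW"), as.raw(c(0, 0)),
      u32(length(pxr)), pxr))
  con <- file(path, "wb")
  writeBin(c(raw(128), charToRaw("DICM"), body), con)
  close(con)
  invisible(path)
}

# ---- cached benchmark ensembles (heavy; shared across acceptance tests) ----

.bench_cache <- new.env(parent = emptyenv())

cached_bench <- function(key, conditions, methods, n_reps = 50, seed = 1) {
  if (is.null(.bench_cache[[key]]))
    .bench_cache[[key]] <- run_benchmark(conditions, methods,
                                         n_reps = n_reps, seed = seed)
  .bench_cache[[key]]
}

bench_dsa6 <- function() {
  cached_bench(
    "dsa6",
    data.frame(shape = "straight", modality = "DSA", sampling_rate = 6),
    data.frame(algorithm = c("cc", "pp", "cc"),
               fit_model = c("gamma_variate", "gamma_variate", "none")))
}

bench_dsa3 <- function() {
  cached_bench(
    "dsa3",
    data.frame(shape = "straight", modality = "DSA", sampling_rate = 3),
    data.frame(algorithm = "cc", fit_model = "gamma_variate"))
}

bench_fluoro10 <- function() {
  cached_bench(
    "fluoro10",
    data.frame(shape = "straight", modality = "FLUORO", sampling_rate = 10),
    data.frame(algorithm = "cc", fit_model = "gamma_variate"))
}

mean_err <- function(bench, alg, fm) {
  sel <- bench$algorithm == alg & bench$fit_model == fm & bench$status == "ok"
  mean(bench$error_pct[sel])
}
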