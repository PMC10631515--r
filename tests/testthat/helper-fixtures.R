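# Small in-code fixtures shared across test files.

# constant-valued map with a wide-pitch grid so circles fit in few pixels
flat_map <- function(value = 100, n = 20, pitch = 0.3, ...) {
  rnflt_map(matrix(value, n, n), pixel_pitch = pitch, ...)
}

# map + disc + mask triple with chosen sub-floor pixels
map_with_artifacts <- function(n = 10, low_idx = NULL, low_value = 30,
                               disc_idx = NULL, pitch = 0.3) {
  v <- matrix(100, n, n)
  if (!is.null(low_idx)) v[low_idx] <- low_value
  m <- rnflt_map(v, pixel_pitch = pitch)
  dm <- matrix(FALSE, n, n)
  if (!is.null(disc_idx)) dm[disc_idx] <- TRUE
  list(map = m, disc = disc_mask(m, mask = dm))
}

# quick eligible VF series with exact values (noise-free unless asked)
toy_vf_series <- function(md = c(0, -1, -2, -3, -4),
                          years = 0:4, td_value = md, vfi = NULL,
                          fl = 0, fp = 0, fn = 0, eye_id = "E1") {
  n <- length(md)
  ex <- data.frame(exam_date = as.Date("2015-01-01") + round(years * 365.25),
                   md = md,
                   vfi = if (is.null(vfi)) pmin(pmax(100 + 2.1 * md, 0), 100)
                         else vfi)
  ex[paste0("td_", 1:52)] <- matrix(rep(td_value, 52), nrow = n)
  ex$fixation_loss <- rep_len(fl, n)
  ex$false_pos <- rep_len(fp, n)
  ex$false_neg <- rep_len(fn, n)
  vf_series(eye_id, ex)
}

# small ready-made pseudo-artifact corpus (cached per session)
tiny_corpus <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      cohort <- simulate_cohort(n_patients = 12, size = 32, donor_prob = 0.5,
                                donor_ar_range = c(0.08, 0.2), seed = 11)
      val <<- build_pseudo_corpus(cohort, seed = 12)
    }
    val
  }
})
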