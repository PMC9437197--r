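# Reference pressure for dB SPL: 20 micropascal. Waveforms are in pascal so
# that a digital RMS maps directly onto a sound pressure level.
P_REF_PA <- 20e-6

db_to_power <- function(db) 10^(db / 10)
power_to_db <- function(p) 10 * log10(p)

spl_to_rms_pa <- function(db_spl) P_REF_PA * 10^(db_spl / 20)

rms <- function(x) sqrt(mean(x^2))

rms_db_spl <- function(x) 20 * log10(rms(x) / P_REF_PA)

# Width (Hz) of the intersection of two frequency intervals; 0 if disjoint.
overlap_width <- function(lo1, hi1, lo2, hi2) {
  max(0, min(hi1, hi2) - max(lo1, lo2))
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    abort(paste0("`", name, "` must be positive and finite"))
  }
  invisible(x)
}
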