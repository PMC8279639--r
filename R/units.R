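# Unit conventions used throughout: lengths in Angstrom, times in fs,
# masses in amu, frequencies in cm^-1.

# 1 cycle/fs expressed in wavenumbers: 1e15 Hz / c[cm/s]
CM1_PER_CYCLE_FS <- 33356.40952

#' Convert a frequency in cycles per femtosecond to wavenumbers
#'
#' @param f frequency in cycles/fs
#' @return frequency in cm^-1
#' @keywords internal
cycles_fs_to_cm1 <- function(f) f * CM1_PER_CYCLE_FS

#' @rdname cycles_fs_to_cm1
#' @param nu frequency in cm^-1
#' @keywords internal
cm1_to_cycles_fs <- function(nu) nu / CM1_PER_CYCLE_FS
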