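Package: pwvrecon
Title: Pulse Wave Velocity from Low-Rate Pulse Recordings via Bandlimited Reconstruction
Version: 0.1.0
Authors@R:
    person("pwvrecon", "maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Tools for measuring arterial Pulse Wave Velocity (PWV) from
    two-channel pulse recordings acquired at low sampling rates. Implements
    bandlimited (Nyquist-Shannon) signal reconstruction by rational polyphase
    FIR resampling, zero-phase low-pass filtering, grid-based systolic peak
    detection, per-beat pulse transit time (PTT) and PWV estimation with
    physiological validity filtering, and reconstruction-fidelity diagnostics
    (zero-normalized cross-correlation, Blackman-windowed segment spectra,
    aliasing analysis). Includes a synthetic two-channel pulse generator with
    exactly known ground truth, a plain-text recording format, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
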