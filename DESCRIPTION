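Package: pcgmap
Title: Multichannel Phonocardiogram Processing and Cardiac Acoustic Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for conditioning multichannel chest-surface heart sound
    (phonocardiogram) recordings together with a synchronized ECG reference,
    locating the sensor array on a standard skeleton image by landmark-based
    similarity registration from a chest photograph, and rendering
    time-resolved cardiac acoustic maps (heart sound modulus heatmaps) over
    the cardiac cycle. Includes ensemble mean-range normalization, zero-phase
    Butterworth band-pass filtering, coiflet wavelet denoising with the
    universal (sqtwolog) soft threshold, Pan-Tompkins R-wave detection,
    HSV-threshold plus circle-Hough colored marker extraction, thin-plate
    spline scattered interpolation, an HSL blue-to-red modulus colormap, and
    closed-form sensor front-end characterization (RC cut-offs, gain chains,
    power spectral density center frequency, consistency difference rates,
    signal-to-noise ratio). A synthetic-data generator emulates the 72-channel
    recording geometry so the whole pipeline is testable without hardware.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    png,
    pracma,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
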