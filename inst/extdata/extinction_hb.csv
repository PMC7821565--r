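wavelength_nm,hbo,hbb,units,source
760,1486.5865,3843.707,cm^-1 M^-1,"Tabulated hemoglobin molar extinction compilation (S. Prahl, Oregon Medical Laser Center, 1998), as distributed with common fNIRS toolchains"
850,2526.391,1798.643,cm^-1 M^-1,"Tabulated hemoglobin molar extinction compilation (S. Prahl, Oregon Medical Laser Center, 1998), as distributed with common fNIRS toolchains"
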