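# Named analysis regions (see read_regions()). These mirror the built-in
# registry: the coastal Dakar Nino Index band, the Nino3.4 box, the North
# Atlantic AMV box and the 60S-60N global band.
CDNI:
  kind: coastal_band
  lat_min: 9
  lat_max: 18
  band_width: 2
nino34:
  kind: latlon_box
  lat_min: -5
  lat_max: 5
  lon_min: -170
  lon_max: -120
amv_north_atlantic:
  kind: latlon_box
  lat_min: 0
  lat_max: 60
  lon_min: -80
  lon_max: 0
global_band:
  kind: latlon_box
  lat_min: -60
  lat_max: 60
  lon_min: -180
  lon_max: 179.999
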