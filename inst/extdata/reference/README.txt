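Curated reference GRN specifications are not redistributed with this
package.  To run the published-network reproductions, place here, for each
network (pancreas, rscn2010, rscn2020):

  <name>_edges.csv  columns: source,target,sign   (sign is +1 or -1)
  <name>_fps.csv    columns: name,<one 0/1 column per node>

built from the corresponding supplementary tables of the source
publications.  See read_network_config() for the exact format.
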