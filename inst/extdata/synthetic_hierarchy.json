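{"id":1,"name":"root","acronym":"root","children":[{"id":2,"name":"ISO","acronym":"ISO","children":[{"id":5,"name":"ISO.1","acronym":"ISO.1","children":[{"id":11,"name":"ISO.1.1","acronym":"ISO.1.1","children":[]},{"id":12,"name":"ISO.1.2","acronym":"ISO.1.2","children":[]}]},{"id":6,"name":"ISO.2","acronym":"ISO.2","children":[{"id":13,"name":"ISO.2.1","acronym":"ISO.2.1","children":[]},{"id":14,"name":"ISO.2.2","acronym":"ISO.2.2","children":[]}]}]},{"id":3,"name":"CB","acronym":"CB","children":[{"id":7,"name":"CB.1","acronym":"CB.1","children":[{"id":15,"name":"CB.1.1","acronym":"CB.1.1","children":[]},{"id":16,"name":"CB.1.2","acronym":"CB.1.2","children":[]}]},{"id":8,"name":"CB.2","acronym":"CB.2","children":[{"id":17,"name":"CB.2.1","acronym":"CB.2.1","children":[]},{"id":18,"name":"CB.2.2","acronym":"CB.2.2","children":[]}]}]},{"id":4,"name":"OTH1","acronym":"OTH1","children":[{"id":9,"name":"OTH1.1","acronym":"OTH1.1","children":[{"id":19,"name":"OTH1.1.1","acronym":"OTH1.1.1","children":[]},{"id":20,"name":"OTH1.1.2","acronym":"OTH1.1.2","children":[]}]},{"id":10,"name":"OTH1.2","acronym":"OTH1.2","children":[{"id":21,"name":"OTH1.2.1","acronym":"OTH1.2.1","children":[]},{"id":22,"name":"OTH1.2.2","acronym":"OTH1.2.2","children":[]}]}]}]}
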