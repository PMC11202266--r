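fish_id	most_advanced_stage	dominant_stage	compartment_size	observations
188	SPA	SPA	small	
233	SPA	SPA	small	
240	SPA	SPA	small	
176	SPA	SPA	small	
193	SPA	SPA	small	
203	SPA	SPA	medium	tubules, high cell division
236	SPA	SPA	small	
160	SPA	SPA	medium	tubules, high cell division
198	SPA	SPA	small	oocytes
255	SPA	SPA	small	oocytes
250	SPA	SPA	small	
221	SPA	SPA	small	oocytes
226	SPA	SPA	small	
180	SPA	SPA	small	
184	SPT	SPB	medium	
190	SPT	SPC	large	
213	SPC	SPC	large	
245	SZ	SPC	large	
211	SZ	SPC	large	
202	SZ	SPC	large	
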