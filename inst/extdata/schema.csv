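table,column,type,description
sites,site_id,character,unique pasture identifier
sites,landscape_id,character,identifier pairing the two pastures of one landscape
sites,region,character,biogeographical region label
sites,regime,character,management regime: low or high
sites,latitude,numeric,decimal degrees in [-90; 90]
sites,longitude,numeric,decimal degrees in [-180; 180]
covariates,site_id,character,pasture identifier
covariates,cattle_density,numeric,animals per hectare (> 0)
covariates,anthelmintic_use,integer,deworming applications per year (0..4)
covariates,land_history,numeric,years of continuous cattle use (>= 0)
covariates,bio*,numeric,13 bioclimatic columns; any 13 names prefixed 'bio'
dungpats,site_id,character,pasture identifier
dungpats,unit_id,character,unique dung pat identifier
dungpats,role,character,experimental or control
dungpats,IWwet,numeric,initial wet weight (g; > 0)
dungpats,FWwet,numeric,final wet weight (g; >= FWdry)
dungpats,FWdry,numeric,final dry weight (g; >= 0)
dungpats,exposure,numeric,field exposure (h; nominal 48)
occurrences,site_id,character,pasture identifier
occurrences,species_id,character,species or morphospecies identifier
occurrences,abundance,integer,individuals trapped (>= 0)
occurrences,guild,character,paracoprid/telecoprid/endocoprid/kleptocoprid (aliases: tunneler/roller/dweller/kleptoparasite)
traits,species_id,character,species identifier
traits,individual_id,character,measured individual (<= 10 per species per locality)
traits,head_length,numeric,mm (> 0)
traits,head_width,numeric,mm
traits,pronotum_length,numeric,mm
traits,pronotum_width,numeric,mm
traits,pronotum_height,numeric,mm
traits,elytra_length,numeric,mm
traits,protibia_length,numeric,mm
traits,protibia_width,numeric,mm
traits,metatibia_length,numeric,mm
traits,biomass,numeric,dry biomass (g)
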